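#' Binding state vector
#'
#' @param r free antigens per cell.
#' @param A0 free antibodies.
#' @param A1 monovalently bound antibodies.
#' @param A2 bivalently bound antibodies.
#' @param t time (s).
#' @return An object of class `binding_state`.
#' @export
binding_state <- function(r, A0, A1, A2, t = NA_real_) {
  v <- c(r = r, A0 = A0, A1 = A1, A2 = A2)
  if (any(!is.finite(v))) stop("binding state components must be finite")
  if (any(v < -1e-9 * max(1, max(abs(v)))))
    stop("binding state components must be nonnegative")
  structure(list(r = r, A0 = A0, A1 = A1, A2 = A2, t = t),
            class = "binding_state")
}

#' Full kinetic right-hand side
#'
#' Time derivatives of (r, A0, A1, A2) under mass action. The statistical
#' factor of 2 on the association term 2*k1*r*A0 reflects the two equivalent
#' free arms of an antibody in solution; the factor of 2 on 2*koff*A2
#' reflects the two equivalent bound arms of a bivalently bound antibody.
#'
#' @param state a [binding_state()] or named list with r, A0, A1, A2.
#' @param params a [model_params()].
#' @return Named numeric vector of derivatives (dr, dA0, dA1, dA2).
#' @export
rhs_full <- function(state, params) {
  r <- state$r; A0 <- state$A0; A1 <- state$A1; A2 <- state$A2
  if (any(c(r, A0, A1, A2) < 0)) stop("state components must be nonnegative")
  k1 <- params$k1; k2 <- params$k2; koff <- params$koff
  dr  <- -2 * k1 * r * A0 + koff * A1 - k2 * r * A1 + 2 * koff * A2
  dA0 <- -2 * k1 * r * A0 + koff * A1
  dA1 <-  2 * k1 * r * A0 - koff * A1 - k2 * r * A1 + 2 * koff * A2
  dA2 <-  k2 * r * A1 - 2 * koff * A2
  c(dr = dr, dA0 = dA0, dA1 = dA1, dA2 = dA2)
}

#' Reduced kinetic right-hand side
#'
#' Derivatives of (A1, A2) after eliminating the free pools through the two
#' conservation laws A0 = Atot - A1 - A2 and r = rtot - A1 - 2*A2.
#'
#' @param A1 monovalently bound antibodies.
#' @param A2 bivalently bound antibodies.
#' @param params a [model_params()].
#' @return Named numeric vector (dA1, dA2).
#' @export
rhs_reduced <- function(A1, A2, params) {
  if (A1 < 0 || A2 < 0) stop("A1 and A2 must be nonnegative")
  r <- params$rtot - A1 - 2 * A2
  A0 <- params$Atot - A1 - A2
  tol <- 1e-9 * max(1, params$rtot, params$Atot)
  if (r < -tol || A0 < -tol)
    stop("state violates conservation constraints (A1 + 2*A2 <= rtot, A1 + A2 <= Atot)")
  r <- max(r, 0); A0 <- max(A0, 0)
  k1 <- params$k1; k2 <- params$k2; koff <- params$koff
  dA1 <- 2 * k1 * r * A0 - koff * A1 - k2 * r * A1 + 2 * koff * A2
  dA2 <- k2 * r * A1 - 2 * koff * A2
  c(dA1 = dA1, dA2 = dA2)
}

# Newton step -J^-1 f(y) of the reduced system; the analytic Jacobian keeps
# the steady-state distance estimate exact to first order
newton_step_reduced <- function(y, params) {
  A1 <- y[1]; A2 <- y[2]
  k1 <- params$k1; k2 <- params$k2; koff <- params$koff
  r <- max(params$rtot - A1 - 2 * A2, 0)
  A0 <- max(params$Atot - A1 - A2, 0)
  f <- c(2 * k1 * r * A0 - koff * A1 - k2 * r * A1 + 2 * koff * A2,
         k2 * r * A1 - 2 * koff * A2)
  j11 <- -2 * k1 * (A0 + r) - koff - k2 * (r - A1)
  j12 <- -2 * k1 * (2 * A0 + r) + 2 * k2 * A1 + 2 * koff
  j21 <- k2 * (r - A1)
  j22 <- -2 * k2 * A1 - 2 * koff
  det <- j11 * j22 - j12 * j21
  if (!is.finite(det) || abs(det) < 1e-300) return(f / max(params$koff, 1e-300))
  c(-(j22 * f[1] - j12 * f[2]) / det, -(j11 * f[2] - j21 * f[1]) / det)
}

deriv_reduced_desolve <- function(t, y, parms) {
  r <- parms$rtot - y[1] - 2 * y[2]
  A0 <- parms$Atot - y[1] - y[2]
  r <- max(r, 0); A0 <- max(A0, 0)
  dA1 <- 2 * parms$k1 * r * A0 - parms$koff * y[1] -
    parms$k2 * r * y[1] + 2 * parms$koff * y[2]
  dA2 <- parms$k2 * r * y[1] - 2 * parms$koff * y[2]
  list(c(dA1, dA2))
}

#' Simulate the binding trajectory
#'
#' Integrates the reduced system (A1, A2) from the unbound initial condition
#' A1(0) = A2(0) = 0 with a stiff-capable adaptive solver, and reconstructs
#' the free pools from the conservation laws.
#'
#' @param params a [model_params()].
#' @param times numeric vector of output times (s), starting at 0.
#' @param rtol,atol solver relative/absolute tolerances.
#' @return A data.frame with columns t, r, A0, A1, A2.
#' @examples
#' p <- model_params(Ainit = 1e-9)
#' traj <- simulate_binding(p, times = c(0, 10^(0:5)))
#' @export
simulate_binding <- function(params, times, rtol = 1e-10, atol = 1e-6) {
  stopifnot(inherits(params, "model_params"), times[1] == 0)
  out <- deSolve::lsoda(y = c(A1 = 0, A2 = 0), times = times,
                        func = deriv_reduced_desolve, parms = params,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  A1 <- pmax(out[, "A1"], 0); A2 <- pmax(out[, "A2"], 0)
  data.frame(t = out[, "time"],
             r = params$rtot - A1 - 2 * A2,
             A0 = params$Atot - A1 - A2,
             A1 = A1, A2 = A2)
}

#' Integrate the kinetics to steady state
#'
#' Runs the reduced system from the unbound initial condition over successive
#' doublings of the time horizon until both (i) the derivative norm is small
#' relative to the state (and to an absolute floor) and (ii) the state change
#' over the last doubling is below `rel_tol`. Time scales range from
#' sub-second at high dose to ~1e6 s (days) at picomolar dose, so the horizon
#' is adaptive.
#'
#' Convergence is measured by the Newton step of the reduced system: the
#' remaining distance to equilibrium is estimated as |J^-1 f(y)|, with f the
#' reduced right-hand side and J its analytic 2x2 Jacobian. Near equilibrium
#' this equals the true distance to first order, and -- unlike a raw
#' derivative-norm or plateau test -- it is not fooled by the quasi-static
#' phase in which fast monovalent capture has equilibrated while the
#' koff-gated redistribution into bivalent binding is still creeping. The
#' run stops once the estimate falls below `rel_tol` relative to the state
#' (with an absolute floor of `abs_tol * scale` molecules, scale being the
#' smaller conserved total).
#'
#' @param params a [model_params()].
#' @param rel_tol relative tolerance on the extrapolated remaining change.
#' @param abs_tol absolute floor, as a fraction of the smaller conserved
#'   total, under which components are considered converged regardless of
#'   relative change.
#' @param t_max maximum horizon (s) before a convergence error is raised.
#' @return A [binding_state()] at the detected steady state (with `t` the
#'   horizon reached).
#' @export
integrate_to_steady_state <- function(params, rel_tol = 1e-8,
                                      abs_tol = 1e-8, t_max = 1e12) {
  stopifnot(inherits(params, "model_params"))
  if (params$Atot == 0)
    return(binding_state(params$rtot, 0, 0, 0, t = 0))
  if (params$rtot == 0)
    return(binding_state(0, params$Atot, 0, 0, t = 0))

  scale <- max(1, min(params$rtot, 2 * params$Atot))
  floor_abs <- abs_tol * scale
  # start near the fastest relaxation time so early horizons are cheap
  rate0 <- max(params$koff, params$k1 * params$Atot, params$k2 * params$rtot)
  t_hi <- max(1e-3, 0.1 / rate0)
  y <- c(A1 = 0, A2 = 0)
  t_lo <- 0
  atol <- max(1e-10 * scale, 1e-10)
  repeat {
    out <- suppressWarnings(
      deSolve::lsoda(y = y, times = c(t_lo, t_hi),
                     func = deriv_reduced_desolve, parms = params,
                     rtol = 1e-10, atol = atol, maxsteps = 1e6))
    y <- pmax(out[nrow(out), c("A1", "A2")], 0)
    ynorm <- max(sqrt(sum(y^2)), floor_abs)
    step <- newton_step_reduced(y, params)
    if (sqrt(sum(step^2)) <= rel_tol * ynorm) break
    if (t_hi >= t_max) {
      e <- simpleError("steady state not reached within the maximum horizon")
      e$last_state <- binding_state(params$rtot - y[1] - 2 * y[2],
                                    params$Atot - y[1] - y[2],
                                    y[1], y[2], t = t_hi)
      stop(e)
    }
    # keep the solver's error floor well below the convergence threshold
    atol <- max(1e-2 * rel_tol * ynorm, 1e-12)
    t_lo <- t_hi
    t_hi <- t_hi * 2
  }
  binding_state(r = params$rtot - y[1] - 2 * y[2],
                A0 = params$Atot - y[1] - y[2],
                A1 = unname(y[1]), A2 = unname(y[2]), t = t_hi)
}

#' Write a simulated trajectory to CSV
#'
#' @param trajectory a data.frame from [simulate_binding()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
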