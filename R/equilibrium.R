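#' Bivalently bound antibodies from monovalently bound, at steady state
#'
#' In the scaled (hatted) variables xhat = K2 * x, setting the bivalent
#' balance to zero gives A2hat = A1hat * (rtot_hat - A1hat) / (2 * (1 + A1hat)).
#'
#' @param A1hat scaled monovalently bound antibodies (dimensionless).
#' @param rtot_hat scaled total antigen number.
#' @return A2hat (dimensionless). Vectorised.
#' @export
a2_from_a1 <- function(A1hat, rtot_hat) {
  if (any(A1hat < 0)) stop("A1hat must be nonnegative")
  if (any(A1hat > rtot_hat * (1 + 1e-12)))
    stop("A1hat exceeds rtot_hat: no admissible bivalent steady state")
  A1hat * (rtot_hat - A1hat) / (2 * (1 + A1hat))
}

# steady-state balance for the scaled monovalent pool, with the bivalent
# balance already substituted: f(x) = 0 at the equilibrium A1hat.
# f(x) = (R - x) * (2*(1+x)*(A - x) - x*(R - x)) - K21 * x * (1+x)^2
# f(0) = 2*A*R > 0 and f(min(R, A)) < 0, so [0, min(R, A)] always brackets.
hat_balance <- function(x, R, A, K21) {
  (R - x) * (2 * (1 + x) * (A - x) - x * (R - x)) - K21 * x * (1 + x)^2
}

hat_balance_deriv <- function(x, R, A, K21) {
  b <- 2 * (1 + x) * (A - x) - x * (R - x)
  db <- 2 * (A - x) - 2 * (1 + x) - (R - x) + x
  -b + (R - x) * db - K21 * ((1 + x)^2 + 2 * x * (1 + x))
}

#' Cubic coefficients of the scaled equilibrium
#'
#' Eliminating the bivalent pool from the two steady-state balances yields a
#' cubic in the scaled monovalent pool A1hat. In non-divided form,
#' c3*x^3 + c2*x^2 + c1*x + c0 = 0 with
#' c3 = 1 - K21, c2 = 2*(1 - Ainit_hat - K21),
#' c1 = 2*Ainit_hat*(rtot_hat - 1) - (rtot_hat + 1)^2 + 1 - K21,
#' c0 = 2*Ainit_hat*rtot_hat.
#' Dividing by (1 - K21) gives the conventional monic rendering, whose linear
#' coefficient is the alpha reported alongside the cubic. For realistic
#' assay parameters K21 = k2*sigma/kon >> 1 and the sequence (c3, c2, c1, c0)
#' has exactly one sign change, so by Descartes' rule of signs the cubic has
#' exactly one real positive root.
#'
#' @param params a [model_params()].
#' @return A list with c3, c2, c1, c0 (non-divided), alpha (monic linear
#'   coefficient, NA when K21 == 1), and the scaled inputs rtot_hat,
#'   Ainit_hat, K21.
#' @export
build_cubic <- function(params) {
  stopifnot(inherits(params, "model_params"))
  K2 <- params$K2
  if (!is.finite(K2) || K2 <= 0)
    stop("cubic requires k2 > 0 and koff > 0; use solve_monovalent_equilibrium for k2 = 0")
  R <- K2 * params$rtot
  A <- K2 * params$Atot
  K21 <- params$K21
  c3 <- 1 - K21
  c2 <- 2 * (1 - A - K21)
  c1 <- 2 * A * (R - 1) - (R + 1)^2 + 1 - K21
  c0 <- 2 * A * R
  alpha <- if (K21 != 1) c1 / (1 - K21) else NA_real_
  list(c3 = c3, c2 = c2, c1 = c1, c0 = c0, alpha = alpha,
       rtot_hat = R, Ainit_hat = A, K21 = K21)
}

# positive real roots of the (possibly degenerate) cubic, in hatted units
positive_cubic_roots <- function(cc, rel_im = 1e-7) {
  coefs <- c(cc$c0, cc$c1, cc$c2, cc$c3)
  # drop (numerically) vanishing leading coefficients
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  if (length(coefs) <= 1) return(numeric(0))
  z <- polyroot(coefs)
  re <- Re(z)
  keep <- abs(Im(z)) <= rel_im * pmax(abs(re), 1) & re > 0
  sort(re[keep])
}

#' Equilibrium of the bivalent binding model
#'
#' Solves the scaled cubic for the unique positive root, converts back to
#' molecules per cell and reconstructs the bivalent pool and the free pools.
#' The root from the closed-form polynomial solve is polished by Newton
#' iteration on the exact steady-state balance and, if needed, by bracketed
#' bisection on [0, min(rtot_hat, Ainit_hat)], which always brackets the
#' root. Degenerate inputs (rtot = 0 or Atot = 0) short-circuit to the
#' trivial equilibrium, and k2 = 0 delegates to the monovalent closed form.
#'
#' @param params a [model_params()].
#' @return A list of class `equilibrium_result`: A1, A2, r, A0 (molecules per
#'   cell), the scaled root A1hat, and residuals of the two steady-state
#'   balances relative to their largest term.
#' @examples
#' p <- model_params(kon = 1e5, koff = 1e-4, D = 1e-14, rtot = 1e4, Ainit = 1e-10)
#' eq <- solve_bivalent_equilibrium(p)
#' (eq$A1 + 2 * eq$A2) / p$rtot  # antigen occupancy
#' @export
solve_bivalent_equilibrium <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$Atot == 0 || params$rtot == 0)
    return(make_equilibrium_result(0, 0, params))
  if (params$k2 == 0) {
    A1 <- solve_monovalent_equilibrium(params)
    return(make_equilibrium_result(A1, 0, params))
  }
  cc <- build_cubic(params)
  R <- cc$rtot_hat; A <- cc$Ainit_hat; K21 <- cc$K21
  hi <- min(R, A)

  roots <- positive_cubic_roots(cc)
  roots <- roots[roots <= hi * (1 + 1e-9)]
  if (length(roots) > 1) {
    gaps <- diff(roots) / pmax(roots[-length(roots)], 1e-300)
    if (any(gaps > 1e-6))
      stop("multiple admissible positive equilibrium roots: ",
           "model assumptions (K21 >> 1) violated for these parameters")
  }
  x <- if (length(roots) >= 1) min(roots[1], hi) else NA_real_

  f <- function(x) hat_balance(x, R, A, K21)
  # Newton polish on the exact balance; fall back to bisection if it strays
  if (is.finite(x)) {
    for (i in 1:50) {
      fx <- f(x)
      dfx <- hat_balance_deriv(x, R, A, K21)
      if (dfx == 0) break
      step <- fx / dfx
      xn <- x - step
      if (!is.finite(xn) || xn < 0 || xn > hi) break
      x <- xn
      if (abs(step) <= 1e-15 * max(x, 1e-300)) break
    }
  }
  ok <- is.finite(x) && x >= 0 && x <= hi && {
    fx <- abs(f(x))
    fscale <- abs(R * 2 * A) + abs(K21 * x * (1 + x)^2) + abs(x^3)
    fx <= 1e-8 * max(fscale, 1e-300)
  }
  if (!ok) {
    # guaranteed bracket: f(0) = 2*A*R > 0, f(hi) < 0
    x <- stats::uniroot(f, lower = 0, upper = hi, tol = .Machine$double.eps,
                        maxiter = 200)$root
    # one more Newton pass for full precision
    for (i in 1:5) {
      dfx <- hat_balance_deriv(x, R, A, K21)
      if (dfx == 0) break
      xn <- x - f(x) / dfx
      if (!is.finite(xn) || xn < 0 || xn > hi) break
      x <- xn
    }
  }
  A1 <- x / params$K2
  A2 <- a2_from_a1(x, R) / params$K2
  make_equilibrium_result(A1, A2, params, A1hat = x)
}

#' Equilibrium of the monovalent binding model
#'
#' With the cross-linking arm disabled (k2 = 0, A2 = 0) the steady state
#' satisfies the quadratic 2*K1*(rtot - A1)*(Atot - A1) = A1. The physically
#' admissible root lies in [0, min(rtot, Atot)] and is computed in the
#' cancellation-safe form 2c / (b + sqrt(b^2 - 4ac)).
#'
#' @param params a [model_params()].
#' @return A1* in molecules per cell.
#' @export
solve_monovalent_equilibrium <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$Atot == 0 || params$rtot == 0) return(0)
  K1 <- params$K1
  if (!is.finite(K1) || K1 < 0) stop("K1 must be finite and nonnegative")
  if (K1 == 0) return(0)
  a <- 2 * K1
  b <- 2 * K1 * (params$rtot + params$Atot) + 1
  cc <- 2 * K1 * params$rtot * params$Atot
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("negative discriminant in monovalent equilibrium")
  2 * cc / (b + sqrt(disc))
}

make_equilibrium_result <- function(A1, A2, params, A1hat = NA_real_) {
  r <- params$rtot - A1 - 2 * A2
  A0 <- params$Atot - A1 - A2
  res <- equilibrium_residuals(A1, A2, params)
  structure(list(A1 = A1, A2 = A2, r = r, A0 = A0, A1hat = A1hat,
                 residuals = res, params = params),
            class = "equilibrium_result")
}

#' Relative residuals of the two steady-state balances
#'
#' Evaluates both reduced-system derivatives at (A1, A2) and scales each by
#' the largest constituent term, giving a dimensionless check that a
#' candidate equilibrium actually zeroes the kinetics.
#'
#' @param A1,A2 candidate equilibrium (molecules per cell).
#' @param params a [model_params()].
#' @return Named vector (mono, bi) of relative residuals.
#' @export
equilibrium_residuals <- function(A1, A2, params) {
  r <- max(params$rtot - A1 - 2 * A2, 0)
  A0 <- max(params$Atot - A1 - A2, 0)
  k1 <- params$k1; k2 <- params$k2; koff <- params$koff
  terms1 <- c(2 * k1 * r * A0, koff * A1, k2 * r * A1, 2 * koff * A2)
  terms2 <- c(k2 * r * A1, 2 * koff * A2)
  d1 <- terms1[1] - terms1[2] - terms1[3] + terms1[4]
  d2 <- terms2[1] - terms2[2]
  c(mono = if (max(terms1) > 0) abs(d1) / max(terms1) else 0,
    bi = if (max(terms2) > 0) abs(d2) / max(terms2) else 0)
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Equilibrium binding state (molecules per cell)\n")
  cat(sprintf("  A1 = %.6g, A2 = %.6g, r = %.6g, A0 = %.6g\n",
              x$A1, x$A2, x$r, x$A0))
  cat(sprintf("  balance residuals: mono %.2e, bi %.2e\n",
              x$residuals["mono"], x$residuals["bi"]))
  invisible(x)
}

#' Serialise an equilibrium result to JSON
#'
#' @param eq an `equilibrium_result`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
equilibrium_to_json <- function(eq, path = NULL) {
  stopifnot(inherits(eq, "equilibrium_result"))
  p <- eq$params
  rec <- list(
    inputs = list(kon = p$kon, koff = p$koff, D = p$D, rtot = p$rtot,
                  Ainit = p$Ainit, Atot = p$Atot, sigma = p$sigma,
                  k1 = p$k1, k2 = p$k2, K21 = p$K21),
    A1 = eq$A1, A2 = eq$A2, r = eq$r, A0 = eq$A0,
    residuals = as.list(eq$residuals)
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
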