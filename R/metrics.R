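#' Equilibrium binding-state summary metrics
#'
#' The five quantities tracked throughout the package, computed from the
#' equilibrium pools of monovalently (A1) and bivalently (A2) bound
#' antibodies:
#' \itemize{
#'   \item `A1_frac` = A1 / (A1 + A2), the monovalently bound fraction;
#'   \item `A2_frac` = A2 / (A1 + A2), the bivalently bound fraction;
#'   \item `occupancy` = (A1 + 2*A2) / rtot, the antigen occupancy R-bar;
#'   \item `bound_ratio` = (A1 + A2) / rtot, bound antibody per antigen B-bar;
#'   \item `total_bound` = A1 + A2, total bound antibodies B-tot (molecules).
#' }
#' Occupancy and bound-antibody numbers are proxies for effector-function
#' (e.g. ADCC) potency and efficacy.
#'
#' When no antibody is bound (A1 + A2 = 0) the two fractions are undefined;
#' they are returned as NA with `no_binding = TRUE` rather than as 0/0, so
#' dose sweeps that include a zero dose do not silently propagate NaN.
#'
#' @param A1 monovalently bound antibodies at equilibrium (molecules).
#' @param A2 bivalently bound antibodies at equilibrium (molecules).
#' @param rtot total antigens per cell.
#' @return An object of class `binding_metrics` (a list with the five fields
#'   plus `no_binding`).
#' @examples
#' binding_metrics(A1 = 100, A2 = 450, rtot = 1e4)
#' @export
binding_metrics <- function(A1, A2, rtot) {
  if (A1 < 0 || A2 < 0) stop("A1 and A2 must be nonnegative")
  if (rtot <= 0) stop("rtot must be positive to define per-antigen metrics")
  if (A1 + 2 * A2 > rtot * (1 + 1e-9))
    stop("occupancy constraint violated: A1 + 2*A2 exceeds rtot")
  bound <- A1 + A2
  no_binding <- bound == 0
  structure(list(
    A1_frac = if (no_binding) NA_real_ else A1 / bound,
    A2_frac = if (no_binding) NA_real_ else A2 / bound,
    occupancy = min((A1 + 2 * A2) / rtot, 1),
    bound_ratio = bound / rtot,
    total_bound = bound,
    no_binding = no_binding
  ), class = "binding_metrics")
}

#' Metrics of an equilibrium result
#'
#' Convenience wrapper applying [binding_metrics()] to a solved equilibrium.
#'
#' @param eq an `equilibrium_result` from [solve_bivalent_equilibrium()].
#' @return A `binding_metrics` object.
#' @export
metrics_of <- function(eq) {
  stopifnot(inherits(eq, "equilibrium_result"))
  binding_metrics(eq$A1, eq$A2, eq$params$rtot)
}

#' @export
print.binding_metrics <- function(x, ...) {
  cat("Equilibrium binding metrics\n")
  if (x$no_binding) {
    cat("  no antibody bound: bound fractions undefined\n")
  } else {
    cat(sprintf("  monovalent fraction A1  = %.4g\n", x$A1_frac))
    cat(sprintf("  bivalent fraction   A2  = %.4g\n", x$A2_frac))
  }
  cat(sprintf("  antigen occupancy   R   = %.4g\n", x$occupancy))
  cat(sprintf("  bound ratio         B   = %.4g\n", x$bound_ratio))
  cat(sprintf("  total bound         Btot= %.6g molecules\n", x$total_bound))
  invisible(x)
}

# internal: metrics as a plain one-row data.frame (NA fractions preserved)
metrics_row <- function(m) {
  data.frame(A1_frac = m$A1_frac, A2_frac = m$A2_frac,
             occupancy = m$occupancy, bound_ratio = m$bound_ratio,
             total_bound = m$total_bound)
}
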