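#' Log-spaced dose grid
#'
#' @param min,max molar dose range (default 1e-13 to 1e-3 M).
#' @param n number of points (default 121, log-spaced).
#' @return Strictly increasing numeric vector of molar doses.
#' @export
dose_grid <- function(min = 1e-13, max = 1e-3, n = 121) {
  if (!(min > 0 && max > min)) stop("dose grid requires 0 < min < max")
  if (n < 2) stop("dose grid needs at least 2 points")
  10^seq(log10(min), log10(max), length.out = n)
}

signal_kinds <- c("total_bound", "occupancy", "bound_ratio",
                  "A1_frac", "A2_frac")

# equilibrium metric value at one dose; monovalent valency sets k2 = 0, A2 = 0
equilibrium_signal <- function(base, Ainit, valency) {
  p <- base
  p$Atot <- Ainit * base$sigma
  p$Ainit <- Ainit
  if (valency == "monovalent") {
    A1 <- solve_monovalent_equilibrium(p)
    A2 <- 0
  } else {
    eq <- solve_bivalent_equilibrium(p)
    A1 <- eq$A1; A2 <- eq$A2
  }
  list(A1 = A1, A2 = A2)
}

#' Equilibrium dose sweep
#'
#' Evaluates the equilibrium value of a binding metric at each dose of a
#' grid, for a bivalent antibody or for its monovalent analogue (cross-link
#' rate k2 = 0, so A2 = 0 throughout).
#'
#' @param params a [model_params()]; its `Ainit`/`Atot` are overridden by
#'   the grid doses.
#' @param grid molar doses from [dose_grid()].
#' @param signal_kind one of `"total_bound"`, `"occupancy"`, `"bound_ratio"`,
#'   `"A1_frac"`, `"A2_frac"`.
#' @param valency `"bivalent"` (default) or `"monovalent"`.
#' @return An object of class `response_curve`: a data.frame with columns
#'   Ainit, A1, A2, A1_frac, A2_frac, occupancy, bound_ratio, total_bound,
#'   plus attributes `signal_kind`, `valency` and a `signal` column holding
#'   the selected metric.
#' @examples
#' p <- model_params(rtot = 1e4)
#' rc <- sweep_dose(p, dose_grid(n = 41), "bound_ratio")
#' head(rc)
#' @export
sweep_dose <- function(params, grid = dose_grid(),
                       signal_kind = c("total_bound", "occupancy",
                                       "bound_ratio", "A1_frac", "A2_frac"),
                       valency = c("bivalent", "monovalent")) {
  stopifnot(inherits(params, "model_params"))
  signal_kind <- match.arg(signal_kind)
  valency <- match.arg(valency)
  if (any(diff(grid) <= 0) || any(grid <= 0))
    stop("dose grid must be strictly increasing and positive")
  rows <- lapply(grid, function(a) {
    st <- tryCatch(equilibrium_signal(params, a, valency),
                   error = function(e)
                     stop("equilibrium failed at dose ", signif(a, 4), " M: ",
                          conditionMessage(e), call. = FALSE))
    if (params$rtot == 0) {
      data.frame(Ainit = a, A1 = 0, A2 = 0, A1_frac = NA_real_,
                 A2_frac = NA_real_, occupancy = 0, bound_ratio = 0,
                 total_bound = 0)
    } else {
      m <- binding_metrics(st$A1, st$A2, params$rtot)
      cbind(data.frame(Ainit = a, A1 = st$A1, A2 = st$A2), metrics_row(m))
    }
  })
  out <- do.call(rbind, rows)
  out$signal <- out[[signal_kind]]
  attr(out, "signal_kind") <- signal_kind
  attr(out, "valency") <- valency
  attr(out, "params") <- params
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Half-maximal effective concentration of a response curve
#'
#' EC50 is defined directly on the model curve: the first dose (interpolated
#' log-linearly in dose, linearly in signal) at which the signal crosses half
#' of its maximum over the grid. For a biphasic curve this is the first
#' crossing.
#'
#' @param curve a `response_curve` from [sweep_dose()], or a data.frame with
#'   columns `Ainit` and `signal`.
#' @return A list of class `ec50_result`: `ec50` (M), `max_signal`,
#'   `crossing_index` (left index of the grid interval containing the
#'   crossing).
#' @export
ec50 <- function(curve) {
  dose <- curve$Ainit
  sig <- curve$signal
  if (any(!is.finite(sig))) stop("response curve contains non-finite signal")
  smax <- max(sig)
  if (smax <= 0) stop("EC50 undefined: response curve has no positive signal")
  half <- smax / 2
  idx <- which(sig >= half)[1]
  if (idx == 1L) {
    ec <- dose[1]
    ci <- 1L
  } else {
    i0 <- idx - 1L
    # linear in signal vs log10(dose)
    w <- (half - sig[i0]) / (sig[idx] - sig[i0])
    ec <- 10^(log10(dose[i0]) + w * (log10(dose[idx]) - log10(dose[i0])))
    ci <- i0
  }
  structure(list(ec50 = ec, max_signal = smax, crossing_index = ci),
            class = "ec50_result")
}

#' Avidity shift between bivalent and monovalent binding
#'
#' delta EC50 = log10(EC50_monovalent / EC50_bivalent) for the same
#' parameters, the package's measure of the avidity effect: how much less
#' antibody a bivalent binder needs to reach half-maximal signal than a
#' one-armed but otherwise identical antibody.
#'
#' @param params a [model_params()].
#' @param grid molar dose grid.
#' @param signal_kind metric defining the binding signal (default
#'   `"total_bound"`).
#' @return A list of class `avidity_shift`: `delta_ec50`,
#'   `ec50_monovalent`, `ec50_bivalent`.
#' @export
delta_ec50 <- function(params, grid = dose_grid(),
                       signal_kind = c("total_bound", "occupancy",
                                       "bound_ratio")) {
  signal_kind <- match.arg(signal_kind)
  biv <- ec50(sweep_dose(params, grid, signal_kind, "bivalent"))
  mono <- ec50(sweep_dose(params, grid, signal_kind, "monovalent"))
  structure(list(delta_ec50 = log10(mono$ec50 / biv$ec50),
                 ec50_monovalent = mono$ec50,
                 ec50_bivalent = biv$ec50,
                 signal_kind = signal_kind),
            class = "avidity_shift")
}

#' Avidity-shift heatmap over antigen density and binding affinity
#'
#' Computes delta EC50 over a grid of total antigen numbers rtot and
#' dissociation constants KD at a fixed antigen diffusion coefficient. The
#' KD axis is realised by fixing kon and setting koff = KD * kon, which
#' propagates KD into the cross-linking equilibrium constant K2 = k2/koff as
#' the avidity physics requires.
#'
#' @param rtot_grid antigen numbers (default 16 log-spaced in 1e3..1e6).
#' @param KD_grid dissociation constants in M (default 16 log-spaced in
#'   1e-10..1e-6).
#' @param D antigen diffusion coefficient (m^2 s^-1).
#' @param signal_kind metric defining the binding signal.
#' @param kon fixed association rate (s^-1 M^-1).
#' @param grid molar dose grid used for both EC50s.
#' @param geometry an [assay_geometry()].
#' @return A long-format data.frame with columns rtot, KD, koff,
#'   delta_ec50, ec50_monovalent, ec50_bivalent, error (NA_character_ when
#'   the cell succeeded).
#' @export
avidity_heatmap <- function(rtot_grid = 10^seq(3, 6, length.out = 16),
                            KD_grid = 10^seq(-10, -6, length.out = 16),
                            D = 1e-14,
                            signal_kind = c("total_bound", "occupancy",
                                            "bound_ratio"),
                            kon = 1e5, grid = dose_grid(),
                            geometry = assay_geometry()) {
  signal_kind <- match.arg(signal_kind)
  cells <- expand.grid(rtot = rtot_grid, KD = KD_grid,
                       KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    rt <- cells$rtot[i]; kd <- cells$KD[i]
    res <- tryCatch({
      p <- model_params(kon = kon, koff = kd * kon, D = D, rtot = rt,
                        geometry = geometry)
      d <- delta_ec50(p, grid, signal_kind)
      data.frame(rtot = rt, KD = kd, koff = kd * kon,
                 delta_ec50 = d$delta_ec50,
                 ec50_monovalent = d$ec50_monovalent,
                 ec50_bivalent = d$ec50_bivalent,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(rtot = rt, KD = kd, koff = kd * kon,
                 delta_ec50 = NA_real_, ec50_monovalent = NA_real_,
                 ec50_bivalent = NA_real_, error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, out)
}

#' Equilibrium-metric heatmap over antigen density and dose
#'
#' Companion map to [avidity_heatmap()]: a chosen equilibrium metric over a
#' grid of total antigen numbers and antibody doses at fixed rates.
#'
#' @param rtot_grid antigen numbers.
#' @param Ainit_grid molar doses.
#' @param params a [model_params()] supplying the rates (its rtot/Ainit are
#'   overridden cell by cell).
#' @param signal_kind which metric to report.
#' @return Long-format data.frame with columns rtot, Ainit, value.
#' @export
metric_heatmap <- function(rtot_grid = 10^seq(3, 6, length.out = 25),
                           Ainit_grid = dose_grid(1e-12, 1e-4, 25),
                           params = model_params(),
                           signal_kind = c("occupancy", "bound_ratio",
                                           "A1_frac", "A2_frac",
                                           "total_bound")) {
  signal_kind <- match.arg(signal_kind)
  cells <- expand.grid(rtot = rtot_grid, Ainit = Ainit_grid,
                       KEEP.OUT.ATTRS = FALSE)
  vals <- vapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$rtot <- cells$rtot[i]
    p$K2 <- params$k2 / params$koff  # unchanged, kept explicit
    st <- equilibrium_signal(p, cells$Ainit[i], "bivalent")
    m <- binding_metrics(st$A1, st$A2, p$rtot)
    m[[signal_kind]]
  }, numeric(1))
  cbind(cells, value = vals)
}

#' @export
print.avidity_shift <- function(x, ...) {
  cat(sprintf("Avidity shift (signal: %s)\n", x$signal_kind))
  cat(sprintf("  EC50 monovalent = %.4g M\n", x$ec50_monovalent))
  cat(sprintf("  EC50 bivalent   = %.4g M\n", x$ec50_bivalent))
  cat(sprintf("  delta EC50      = %.4f (log10 shift)\n", x$delta_ec50))
  invisible(x)
}
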