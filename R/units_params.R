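#' Avogadro's number
#'
#' Fixed constant used for all molar-to-molecule conversions (mol^-1).
#' @export
AVOGADRO <- 6.02214e23

#' Assay geometry
#'
#' Describes the physical binding-assay setup: the well volume, the number of
#' target cells in the well and the target cell radius. These determine the
#' molecules-per-cell conversion factor ([conversion_factor()]) and the
#' diffusion-limited cross-linking rate ([k2_diffusion()]).
#'
#' @param Vwell well volume in litres (default 150 ul).
#' @param T0 number of target cells in the well (default 2e5).
#' @param Trad target cell radius in metres (default 8 um).
#' @return An object of class `assay_geometry`.
#' @examples
#' geom <- assay_geometry()
#' conversion_factor(geom)
#' @export
assay_geometry <- function(Vwell = 150e-6, T0 = 2e5, Trad = 8e-6) {
  if (!is.numeric(Vwell) || length(Vwell) != 1L || !is.finite(Vwell) || Vwell <= 0)
    stop("invalid geometry: Vwell must be a single positive number (litres)")
  if (!is.numeric(T0) || length(T0) != 1L || !is.finite(T0) || T0 < 1)
    stop("invalid geometry: T0 must be a single cell count >= 1")
  if (!is.numeric(Trad) || length(Trad) != 1L || !is.finite(Trad) || Trad <= 0)
    stop("invalid geometry: Trad must be a single positive number (metres)")
  structure(list(Vwell = Vwell, T0 = T0, Trad = Trad, Na = AVOGADRO),
            class = "assay_geometry")
}

#' Kinetic rate parameters of the antibody-antigen pair
#'
#' @param kon solution association rate constant (s^-1 M^-1).
#' @param koff dissociation rate constant per bound arm (s^-1).
#' @param D membrane diffusion coefficient of the antigen (m^2 s^-1).
#' @param rAb antibody arm-to-arm reach (metres); only used by the
#'   proximity-based cross-linking estimator.
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(kon = 1e5, koff = 1e-4, D = 1e-14, rAb = 12.5e-9) {
  for (nm in c("kon", "koff", "D", "rAb")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("invalid rate parameter: ", nm, " must be a single nonnegative number")
  }
  structure(list(kon = kon, koff = koff, D = D, rAb = rAb),
            class = "rate_params")
}

#' Molecules-per-cell conversion factor
#'
#' sigma = Vwell * Na / T0 converts a molar antibody concentration into
#' antibody molecules available per target cell. With the default assay
#' (150 ul, 2e5 cells) sigma is approximately 4.5e14 M^-1 cell^-1.
#'
#' @param geometry an [assay_geometry()].
#' @return sigma in M^-1 cell^-1.
#' @export
conversion_factor <- function(geometry) {
  stopifnot(inherits(geometry, "assay_geometry"))
  geometry$Vwell * geometry$Na / geometry$T0
}

#' Antibody molecules per cell for a given dose
#'
#' Atot = Ainit * sigma: the total number of antibody molecules in the well,
#' normalised per target cell.
#'
#' @param Ainit initial antibody concentration (M). May be a vector.
#' @param sigma conversion factor from [conversion_factor()].
#' @return Antibody molecules per cell.
#' @export
antibodies_per_cell <- function(Ainit, sigma) {
  if (any(!is.finite(Ainit)) || any(Ainit < 0))
    stop("Ainit must be nonnegative and finite (molar)")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  Ainit * sigma
}

#' Per-molecule association rate
#'
#' Rescales the solution on-rate kon (s^-1 M^-1) to the number-unit rate
#' k1 = kon / sigma (s^-1 per antibody molecule) used by the model.
#'
#' @param kon solution association rate (s^-1 M^-1).
#' @param sigma conversion factor (M^-1 cell^-1).
#' @return k1 in s^-1 per molecule.
#' @export
k1_from_kon <- function(kon, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (any(kon < 0)) stop("kon must be nonnegative")
  kon / sigma
}

#' Diffusion-limited cross-linking rate
#'
#' First-hitting-time estimate of the rate at which a membrane antigen
#' diffuses within reach of the free arm of a monovalently bound antibody:
#' k2 = D / (4 * pi * Trad^2). This is the package default for the
#' second-arm binding rate.
#'
#' @param D antigen membrane diffusion coefficient (m^2 s^-1).
#' @param Trad target cell radius (m).
#' @return k2 in s^-1 per antigen.
#' @export
k2_diffusion <- function(D, Trad) {
  if (any(D < 0)) stop("D must be nonnegative")
  if (any(!is.finite(Trad)) || any(Trad <= 0)) stop("Trad must be positive")
  D / (4 * pi * Trad^2)
}

#' Proximity-based cross-linking rate
#'
#' Alternative estimator that treats antigens as immobile and rate-limits the
#' second binding event by the effective concentration of antigen within the
#' bound antibody's reach: k2 = (38e3) * kon / (pi * Na * Trad^2 * rAb).
#' The numeric prefactor is used as printed in its source; this estimator is
#' selectable but not the default (see [k2_diffusion()]).
#'
#' @param kon solution association rate (s^-1 M^-1).
#' @param Trad target cell radius (m).
#' @param rAb antibody arm-to-arm reach (m).
#' @return k2 in s^-1 per antigen.
#' @export
k2_proximity <- function(kon, Trad, rAb) {
  if (any(kon < 0)) stop("kon must be nonnegative")
  if (any(Trad <= 0) || any(rAb <= 0)) stop("Trad and rAb must be positive")
  (38e3) * kon / (pi * AVOGADRO * Trad^2 * rAb)
}

#' Fraction of the cell surface swept by one antibody arm
#'
#' The disc of radius rAb swept out by the free arm of a bound antibody,
#' as a fraction of the cell surface area: rAb^2 / (4 * Trad^2). For an IgG
#' (rAb = 12.5 nm) on an 8 um cell this is about 6e-7, which motivates
#' treating antigen diffusion, not proximity, as the rate-limiting step for
#' cross-linking.
#'
#' @param rAb antibody arm-to-arm reach (m).
#' @param Trad target cell radius (m).
#' @return Dimensionless area fraction.
#' @export
arm_reach_fraction <- function(rAb, Trad) {
  if (any(rAb < 0)) stop("rAb must be nonnegative")
  if (any(Trad <= 0)) stop("Trad must be positive")
  rAb^2 / (4 * Trad^2)
}

#' Derived number-unit rate constants
#'
#' Bundles the conversions from laboratory units to the per-cell number units
#' the model runs in: sigma, k1 = kon/sigma, the cross-linking rate k2
#' (diffusion-limited by default), and the equilibrium constants
#' K1 = k1/koff, K2 = k2/koff and K21 = K2/K1.
#'
#' @param rates a [rate_params()].
#' @param geometry an [assay_geometry()].
#' @param k2_method `"diffusion"` (default) or `"proximity"`.
#' @return An object of class `derived_rates` with fields sigma, k1, k2,
#'   K1, K2, K21.
#' @export
derived_rates <- function(rates, geometry = assay_geometry(),
                          k2_method = c("diffusion", "proximity")) {
  stopifnot(inherits(rates, "rate_params"))
  k2_method <- match.arg(k2_method)
  sigma <- conversion_factor(geometry)
  k1 <- k1_from_kon(rates$kon, sigma)
  k2 <- switch(k2_method,
    diffusion = k2_diffusion(rates$D, geometry$Trad),
    proximity = k2_proximity(rates$kon, geometry$Trad, rates$rAb)
  )
  if (rates$koff <= 0)
    stop("koff must be positive to form equilibrium constants")
  structure(list(
    sigma = sigma, k1 = k1, k2 = k2,
    K1 = k1 / rates$koff, K2 = k2 / rates$koff,
    K21 = (k2 / rates$koff) / (k1 / rates$koff),
    k2_method = k2_method
  ), class = "derived_rates")
}

#' Model parameters in per-cell number units
#'
#' The five quantities that drive the kinetic and equilibrium calculations:
#' k1 (s^-1 per antibody), k2 (s^-1 per antigen), koff (s^-1), rtot (antigens
#' per cell) and Atot (antibody molecules per cell). Laboratory-unit inputs
#' are converted here, at the boundary; everything downstream works in
#' molecules and seconds.
#'
#' @param kon solution association rate (s^-1 M^-1).
#' @param koff dissociation rate (s^-1).
#' @param D antigen diffusion coefficient (m^2 s^-1).
#' @param rtot total antigens per cell.
#' @param Ainit initial antibody concentration (M).
#' @param geometry an [assay_geometry()].
#' @param rAb arm-to-arm reach (m), used only by the proximity estimator.
#' @param k2_method `"diffusion"` (default) or `"proximity"`.
#' @return An object of class `model_params` with fields k1, k2, koff, rtot,
#'   Atot plus the originating sigma, kon, Ainit and equilibrium constants.
#' @examples
#' p <- model_params(kon = 1e5, koff = 1e-4, D = 1e-14, rtot = 1e4, Ainit = 1e-10)
#' p$Atot
#' @export
model_params <- function(kon = 1e5, koff = 1e-4, D = 1e-14, rtot = 1e4,
                         Ainit = 1e-10, geometry = assay_geometry(),
                         rAb = 12.5e-9,
                         k2_method = c("diffusion", "proximity")) {
  if (!is.finite(rtot) || rtot < 0) stop("rtot must be nonnegative")
  rates <- rate_params(kon = kon, koff = koff, D = D, rAb = rAb)
  dr <- derived_rates(rates, geometry, match.arg(k2_method))
  structure(list(
    k1 = dr$k1, k2 = dr$k2, koff = koff,
    rtot = rtot, Atot = antibodies_per_cell(Ainit, dr$sigma),
    kon = kon, D = D, Ainit = Ainit,
    sigma = dr$sigma, K1 = dr$K1, K2 = dr$K2, K21 = dr$K21,
    geometry = geometry
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bivalent binding model parameters (molecules per cell, seconds)\n")
  cat(sprintf("  k1   = %.6g /s per antibody   (kon = %.3g /s/M, sigma = %.4g /M/cell)\n",
              x$k1, x$kon, x$sigma))
  cat(sprintf("  k2   = %.6g /s per antigen    (D = %.3g m^2/s)\n", x$k2, x$D))
  cat(sprintf("  koff = %.6g /s\n", x$koff))
  cat(sprintf("  rtot = %.6g antigens/cell, Atot = %.6g antibodies (Ainit = %.3g M)\n",
              x$rtot, x$Atot, x$Ainit))
  cat(sprintf("  K1 = %.4g, K2 = %.4g, K21 = K2/K1 = %.4g\n", x$K1, x$K2, x$K21))
  invisible(x)
}
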