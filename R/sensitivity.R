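#' Parameter ranges for global sensitivity analysis
#'
#' The default ranges are the literature ranges the model was parameterised
#' from: kon in [1e4, 1e6] s^-1 M^-1, koff in [1e-6, 1e-3] s^-1, rtot in
#' [1e4, 1e6] antigens, D in [1e-15, 1e-13] m^2 s^-1, each sampled
#' log-uniformly because every range spans at least two decades, plus an
#' inert `dummy` parameter on [0, 1] (linear) whose estimated index is the
#' Monte-Carlo noise floor of the analysis.
#'
#' @param scale `"log"` (default) or `"linear"` sampling scale for the model
#'   parameters (the dummy is always linear).
#' @return A data.frame with columns name, lower, upper, scale.
#' @export
param_ranges <- function(scale = c("log", "linear")) {
  scale <- match.arg(scale)
  data.frame(
    name = c("kon", "koff", "rtot", "D", "dummy"),
    lower = c(1e4, 1e-6, 1e4, 1e-15, 0),
    upper = c(1e6, 1e-3, 1e6, 1e-13, 1),
    scale = c(scale, scale, scale, scale, "linear"),
    stringsAsFactors = FALSE
  )
}

map_unit_to_range <- function(u, lower, upper, scale) {
  if (scale == "log") {
    if (lower <= 0) stop("log scale requires positive bounds")
    10^(log10(lower) + u * (log10(upper) - log10(lower)))
  } else {
    lower + u * (upper - lower)
  }
}

#' Saltelli cross-sampled design for Sobol indices
#'
#' Draws two quasi-random sample matrices A and B over the parameter ranges
#' and forms the radial-composite blocks AB_i (A with column i replaced from
#' B) and, when `second_order = TRUE`, BA_i. With n parameters the design has
#' N*(2n+2) rows (or N*(n+2) without the second-order blocks), ordered as
#' A, B, AB_1..AB_n, BA_1..BA_n.
#'
#' @param ranges a data.frame as returned by [param_ranges()].
#' @param N base sample size; must be a power of two to preserve the balance
#'   of the quasi-random sequence.
#' @param seed integer seed for the randomising shift of the sequence.
#' @param second_order include the BA blocks needed for second-order indices.
#' @return An object of class `saltelli_design`: list with `X` (the design
#'   matrix, columns named by parameter), `block` (row labels "A", "B",
#'   "AB_<name>", "BA_<name>"), `N`, `params`, `seed`, `second_order`,
#'   `ranges`.
#' @export
saltelli_design <- function(ranges = param_ranges(), N = 1024, seed = 1,
                            second_order = TRUE) {
  req <- c("name", "lower", "upper", "scale")
  if (!all(req %in% names(ranges)))
    stop("ranges must have columns name, lower, upper, scale")
  if (any(ranges$lower >= ranges$upper))
    stop("each parameter needs lower < upper")
  if (N < 2 || bitwAnd(as.integer(N), as.integer(N - 1)) != 0)
    stop("N must be a power of two")
  n <- nrow(ranges)
  U <- sobol_sequence(N, 2L * n, seed = seed)
  Ua <- U[, seq_len(n), drop = FALSE]
  Ub <- U[, n + seq_len(n), drop = FALSE]
  blocks <- list(A = Ua, B = Ub)
  for (i in seq_len(n)) {
    ABi <- Ua; ABi[, i] <- Ub[, i]
    blocks[[paste0("AB_", ranges$name[i])]] <- ABi
  }
  if (second_order) {
    for (i in seq_len(n)) {
      BAi <- Ub; BAi[, i] <- Ua[, i]
      blocks[[paste0("BA_", ranges$name[i])]] <- BAi
    }
  }
  Xu <- do.call(rbind, blocks)
  X <- Xu
  for (j in seq_len(n))
    X[, j] <- map_unit_to_range(Xu[, j], ranges$lower[j], ranges$upper[j],
                                ranges$scale[j])
  colnames(X) <- ranges$name
  structure(list(
    X = X,
    block = rep(names(blocks), each = N),
    N = N, params = ranges$name, seed = seed,
    second_order = second_order, ranges = ranges
  ), class = "saltelli_design")
}

#' Evaluate the equilibrium model over a sensitivity design
#'
#' Solves the bivalent equilibrium for every design row at a fixed antibody
#' dose and returns the three outputs tracked by the sensitivity analysis:
#' antigen occupancy, bound-antibody ratio and total bound antibodies. The
#' `dummy` column (and any column that is not a model parameter) is ignored
#' by the model, which is exactly what its sensitivity index tests.
#'
#' @param design a `saltelli_design` (or any matrix/data.frame with columns
#'   kon, koff, rtot, D).
#' @param Ainit fixed molar antibody dose.
#' @param geometry an [assay_geometry()].
#' @return A data.frame with columns occupancy, bound_ratio, total_bound,
#'   one row per design row.
#' @export
evaluate_outputs <- function(design, Ainit, geometry = assay_geometry()) {
  X <- if (inherits(design, "saltelli_design")) design$X else as.matrix(design)
  need <- c("kon", "koff", "rtot", "D")
  if (!all(need %in% colnames(X)))
    stop("design must provide columns kon, koff, rtot, D")
  sigma <- conversion_factor(geometry)
  Atot <- Ainit * sigma
  n <- nrow(X)
  occ <- numeric(n); br <- numeric(n); tb <- numeric(n)
  for (i in seq_len(n)) {
    p <- structure(list(
      k1 = X[i, "kon"] / sigma,
      k2 = k2_diffusion(X[i, "D"], geometry$Trad),
      koff = X[i, "koff"], rtot = X[i, "rtot"], Atot = Atot,
      kon = X[i, "kon"], D = X[i, "D"], Ainit = Ainit, sigma = sigma,
      K1 = NA_real_, K2 = NA_real_, K21 = NA_real_, geometry = geometry
    ), class = "model_params")
    p$K1 <- p$k1 / p$koff; p$K2 <- p$k2 / p$koff; p$K21 <- p$K2 / p$K1
    eq <- solve_bivalent_equilibrium(p)
    occ[i] <- min((eq$A1 + 2 * eq$A2) / p$rtot, 1)
    br[i] <- (eq$A1 + eq$A2) / p$rtot
    tb[i] <- eq$A1 + eq$A2
  }
  data.frame(occupancy = occ, bound_ratio = br, total_bound = tb)
}

#' Sobol sensitivity indices from a Saltelli design
#'
#' First-order indices use the Saltelli (2010) estimator
#' S_i = mean(f_B * (f_ABi - f_A)) / Var(Y) and total-order indices the
#' Jansen estimator ST_i = mean((f_A - f_ABi)^2) / (2 * Var(Y)), with Var(Y)
#' taken over the pooled A and B blocks. Second-order indices (when the
#' design carries BA blocks and `second_order = TRUE`) use
#' V_ij = mean(f_BAi * f_ABj - f_A * f_B) / Var(Y) minus the first-order
#' parts. Uncertainty is estimated by bootstrap resampling of the N design
#' rows.
#'
#' @param design a `saltelli_design`.
#' @param y numeric output vector, one value per design row.
#' @param second_order compute second-order indices (requires a design built
#'   with `second_order = TRUE`).
#' @param n_boot bootstrap resamples for standard errors (0 disables).
#' @return An object of class `sobol_result`: `indices` (data.frame with
#'   parameter, S1, ST, S1_se, ST_se), optional `second_order` data.frame
#'   (i, j, Sij), `variance`, `N`, `seed`. If the output variance is zero the
#'   indices are NA and `degenerate = TRUE`.
#' @export
sobol_indices <- function(design, y, second_order = FALSE, n_boot = 100) {
  stopifnot(inherits(design, "saltelli_design"))
  if (length(y) != nrow(design$X))
    stop("y must have one value per design row")
  if (any(!is.finite(y))) stop("outputs must be finite")
  if (second_order && !design$second_order)
    stop("design was built without second-order (BA) blocks")
  N <- design$N
  params <- design$params
  getb <- function(b) y[design$block == b]
  fA <- getb("A"); fB <- getb("B")
  fAB <- sapply(params, function(p) getb(paste0("AB_", p)))
  V <- stats::var(c(fA, fB))
  if (!is.finite(V) || V <= 0) {
    idx <- data.frame(parameter = params, S1 = NA_real_, ST = NA_real_,
                      S1_se = NA_real_, ST_se = NA_real_)
    return(structure(list(indices = idx, variance = V, N = N,
                          seed = design$seed, degenerate = TRUE),
                     class = "sobol_result"))
  }
  est <- function(rows) {
    a <- fA[rows]; b <- fB[rows]; ab <- fAB[rows, , drop = FALSE]
    # centring Y removes the mean-offset term that otherwise dominates the
    # first-order estimator when the output is nearly saturated
    mu <- mean(c(a, b))
    a <- a - mu; b <- b - mu; ab <- ab - mu
    v <- stats::var(c(a, b))
    S1 <- colMeans(b * (ab - a)) / v
    ST <- colMeans((a - ab)^2) / (2 * v)
    list(S1 = S1, ST = ST)
  }
  point <- est(seq_len(N))
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(design$seed %% .Machine$integer.max) + 1L)
    bs1 <- matrix(NA_real_, n_boot, length(params))
    bst <- matrix(NA_real_, n_boot, length(params))
    for (k in seq_len(n_boot)) {
      rows <- sample.int(N, N, replace = TRUE)
      e <- est(rows)
      bs1[k, ] <- e$S1; bst[k, ] <- e$ST
    }
    s1_se <- apply(bs1, 2, stats::sd)
    st_se <- apply(bst, 2, stats::sd)
  } else {
    s1_se <- st_se <- rep(NA_real_, length(params))
  }
  idx <- data.frame(parameter = params, S1 = unname(point$S1),
                    ST = unname(point$ST), S1_se = s1_se, ST_se = st_se)
  res <- list(indices = idx, variance = V, N = N, seed = design$seed,
              degenerate = FALSE)
  if (second_order) {
    fBA <- sapply(params, function(p) getb(paste0("BA_", p)))
    mu <- mean(c(fA, fB))
    cA <- fA - mu; cB <- fB - mu
    cAB <- fAB - mu; cBA <- fBA - mu
    n <- length(params)
    rows <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        Vij <- mean(cBA[, i] * cAB[, j] - cA * cB) / V
        Sij <- Vij - point$S1[i] - point$S1[j]
        rows[[length(rows) + 1L]] <-
          data.frame(i = params[i], j = params[j], Sij = Sij)
      }
    }
    res$second_order <- do.call(rbind, rows)
  }
  structure(res, class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("Sobol sensitivity indices (N = %d, Var(Y) = %.4g)\n",
              x$N, x$variance))
  print(x$indices, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Dose-resolved total-order sensitivity experiment
#'
#' Reproduces the dose-series structure of the global sensitivity analysis:
#' for each fixed antibody dose, builds (or reuses) a Saltelli design over
#' the parameter ranges, evaluates the three equilibrium outputs and
#' estimates first- and total-order indices per parameter.
#'
#' @param doses molar antibody doses (default the decade series 1e-11..1e-5).
#' @param ranges parameter ranges, see [param_ranges()].
#' @param N base sample size (power of two).
#' @param seed integer seed.
#' @param outputs which outputs to analyse.
#' @param n_boot bootstrap resamples for index standard errors.
#' @param geometry an [assay_geometry()].
#' @return Long-format data.frame with columns output, Ainit, parameter,
#'   S1, ST, S1_se, ST_se, N, seed.
#' @export
sensitivity_experiment <- function(doses = 10^seq(-11, -5),
                                   ranges = param_ranges(), N = 1024,
                                   seed = 1,
                                   outputs = c("occupancy", "bound_ratio",
                                               "total_bound"),
                                   n_boot = 100,
                                   geometry = assay_geometry()) {
  outputs <- match.arg(outputs, several.ok = TRUE)
  design <- saltelli_design(ranges, N = N, seed = seed, second_order = FALSE)
  rows <- list()
  for (a in doses) {
    Y <- evaluate_outputs(design, a, geometry)
    for (out in outputs) {
      sr <- sobol_indices(design, Y[[out]], n_boot = n_boot)
      df <- sr$indices
      df$output <- out; df$Ainit <- a; df$N <- N; df$seed <- seed
      rows[[length(rows) + 1L]] <- df
    }
  }
  res <- do.call(rbind, rows)
  res[, c("output", "Ainit", "parameter", "S1", "ST", "S1_se", "ST_se",
          "N", "seed")]
}
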