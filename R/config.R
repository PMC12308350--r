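#' Build a validated run configuration
#'
#' A run configuration bundles the experiment name, the model and assay
#' parameters (defaulting to the package's literature values) and the output
#' settings. Unknown keys are rejected so typos surface as configuration
#' errors rather than silently falling back to defaults.
#'
#' @param ... named overrides of the defaults (see Details), or a single
#'   named list of them.
#' @param file optional YAML file whose keys are read first; `...` overrides
#'   file values.
#'
#' @details Recognised keys: `experiment` (one of "equilibrium", "sweep",
#' "fig3", "fig4", "fig5", "fig7", "ec50", "delta-ec50"), the scalar
#' parameters `kon`, `koff`, `D`, `rtot`, `Ainit`, `Vwell`, `T0`, `Trad`,
#' `rAb`, the switches `k2_method` ("diffusion"/"proximity"), `signal_kind`,
#' `scale` ("log"/"linear" sensitivity sampling), the grids `dose_min`,
#' `dose_max`, `dose_n`, `doses`, `rtot_grid`, `KD_grid`, `Ainit_grid`, the
#' sensitivity settings `n_samples`, `n_boot`, and `seed`, `outdir`,
#' `verbose`.
#'
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(..., file = NULL) {
  defaults <- list(
    experiment = "equilibrium",
    kon = 1e5, koff = 1e-4, D = 1e-14, rtot = 1e4, Ainit = 1e-10,
    Vwell = 150e-6, T0 = 2e5, Trad = 8e-6, rAb = 12.5e-9,
    k2_method = "diffusion",
    signal_kind = "total_bound",
    scale = "log",
    dose_min = 1e-13, dose_max = 1e-3, dose_n = 121,
    doses = 10^seq(-11, -5),
    rtot_grid = 10^seq(3, 6, length.out = 16),
    KD_grid = 10^seq(-10, -6, length.out = 16),
    Ainit_grid = 10^seq(-12, -4, length.out = 25),
    n_samples = 1024, n_boot = 100,
    seed = 1, outdir = ".", verbose = TRUE
  )
  user <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config error: file not found: ", file)
    user <- yaml::read_yaml(file)
    if (!is.list(user)) stop("config error: file must contain a mapping")
  }
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1]]))
    dots <- dots[[1]]
  user[names(dots)] <- dots
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(user)] <- user
  experiments <- c("equilibrium", "sweep", "fig3", "fig4", "fig5", "fig7",
                   "ec50", "delta-ec50")
  if (!cfg$experiment %in% experiments)
    stop("config error: experiment must be one of ",
         paste(experiments, collapse = ", "))
  for (k in c("kon", "koff", "D", "rtot", "Ainit", "Vwell", "T0", "Trad",
              "rAb", "dose_min", "dose_max"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] < 0)
      stop("config error: ", k, " must be a single nonnegative number")
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  model_params(kon = cfg$kon, koff = cfg$koff, D = cfg$D, rtot = cfg$rtot,
               Ainit = cfg$Ainit,
               geometry = assay_geometry(cfg$Vwell, cfg$T0, cfg$Trad),
               rAb = cfg$rAb, k2_method = cfg$k2_method)
}

#' Run a configured experiment
#'
#' Dispatches a [run_config()] to the corresponding computation, writes the
#' tabular outputs (CSV) or single-result records (JSON) under
#' `config$outdir`, and returns a result record pairing every output file
#' with the configuration that generated it. Derived rate constants are
#' logged at startup (when `verbose`) so unit errors surface immediately.
#'
#' @param config a `run_config`.
#' @return An object of class `result_record`: list with `config`,
#'   `package_version`, `timestamp`, `files`, `diagnostics`.
#' @examples
#' \donttest{
#' rec <- run_experiment(run_config(experiment = "equilibrium",
#'                                  outdir = tempdir()))
#' rec$files
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  params <- config_params(cfg)
  if (isTRUE(cfg$verbose)) {
    message(sprintf(
      "derived rates: sigma = %.6g /M/cell, k1 = %.6g /s, k2 = %.6g /s, K21 = %.6g",
      params$sigma, params$k1, params$k2, params$K21))
  }
  grid <- dose_grid(cfg$dose_min, cfg$dose_max, cfg$dose_n)
  files <- character(0)
  diagnostics <- list()
  out <- function(name) file.path(cfg$outdir, name)

  if (cfg$experiment == "equilibrium") {
    eq <- solve_bivalent_equilibrium(params)
    f <- out("equilibrium.json")
    equilibrium_to_json(eq, f)
    files <- f
    diagnostics$residuals <- eq$residuals
  } else if (cfg$experiment %in% c("sweep", "fig3")) {
    curves <- lapply(c("bivalent", "monovalent"), function(v)
      cbind(as.data.frame(sweep_dose(params, grid, cfg$signal_kind, v)),
            valency = v))
    tab <- do.call(rbind, curves)
    tab <- cbind(tab, kon = cfg$kon, koff = cfg$koff, D = cfg$D,
                 rtot = cfg$rtot)
    f <- out(paste0(cfg$experiment, "_dose_sweep.csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- f
  } else if (cfg$experiment == "fig4") {
    tabs <- lapply(c("A1_frac", "A2_frac", "occupancy", "bound_ratio"),
                   function(s) cbind(metric_heatmap(cfg$rtot_grid,
                                                    cfg$Ainit_grid,
                                                    params, s),
                                     signal_kind = s))
    tab <- do.call(rbind, tabs)
    f <- out("fig4_metric_heatmaps.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- f
  } else if (cfg$experiment == "fig5") {
    tab <- sensitivity_experiment(doses = cfg$doses,
                                  ranges = param_ranges(cfg$scale),
                                  N = cfg$n_samples, seed = cfg$seed,
                                  n_boot = cfg$n_boot,
                                  geometry = params$geometry)
    f <- out("fig5_sensitivity.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- f
  } else if (cfg$experiment == "fig7") {
    tabs <- lapply(c("total_bound", "occupancy"), function(s)
      cbind(avidity_heatmap(cfg$rtot_grid, cfg$KD_grid, cfg$D, s,
                            kon = cfg$kon, grid = grid,
                            geometry = params$geometry),
            signal_kind = s))
    tab <- do.call(rbind, tabs)
    f <- out("fig7_avidity_heatmaps.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- f
    diagnostics$failed_cells <- sum(!is.na(tab$error))
  } else if (cfg$experiment == "ec50") {
    curve <- sweep_dose(params, grid, cfg$signal_kind, "bivalent")
    e <- ec50(curve)
    f <- out("ec50.json")
    writeLines(jsonlite::toJSON(list(
      signal_kind = cfg$signal_kind, ec50 = e$ec50,
      max_signal = e$max_signal), auto_unbox = TRUE, digits = NA), f)
    files <- f
  } else if (cfg$experiment == "delta-ec50") {
    d <- delta_ec50(params, grid, cfg$signal_kind)
    f <- out("delta_ec50.json")
    writeLines(jsonlite::toJSON(list(
      signal_kind = cfg$signal_kind, delta_ec50 = d$delta_ec50,
      ec50_monovalent = d$ec50_monovalent,
      ec50_bivalent = d$ec50_bivalent), auto_unbox = TRUE, digits = NA), f)
    files <- f
  }

  structure(list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("avidity")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files,
    diagnostics = diagnostics
  ), class = "result_record")
}

#' @export
print.result_record <- function(x, ...) {
  cat(sprintf("avidity run: experiment '%s' (package %s, %s)\n",
              x$config$experiment, x$package_version, x$timestamp))
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}
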