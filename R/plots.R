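need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Plot a dose-response sweep
#'
#' @param curves one `response_curve` or a named list of them (e.g. bivalent
#'   and monovalent) sharing a dose grid.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(curves) {
  need_ggplot()
  if (inherits(curves, "response_curve")) curves <- list(curve = curves)
  tab <- do.call(rbind, lapply(names(curves), function(nm) {
    data.frame(Ainit = curves[[nm]]$Ainit, signal = curves[[nm]]$signal,
               curve = nm)
  }))
  ggplot2::ggplot(tab, ggplot2::aes(x = Ainit, y = signal, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "antibody concentration (M)", y = "signal")
}

#' Plot dose-resolved total-order sensitivity indices
#'
#' @param tab output of [sensitivity_experiment()].
#' @param output which model output to show.
#' @return A ggplot object (grouped bars of ST by dose).
#' @export
plot_sensitivity <- function(tab, output = "occupancy") {
  need_ggplot()
  d <- tab[tab$output == output, ]
  d$dose <- factor(format(d$Ainit, scientific = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = dose, y = ST, fill = parameter)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "antibody concentration (M)",
                  y = "total-order Sobol index", title = output)
}

#' Plot an avidity-shift heatmap
#'
#' @param tab output of [avidity_heatmap()].
#' @return A ggplot object.
#' @export
plot_avidity_heatmap <- function(tab) {
  need_ggplot()
  ggplot2::ggplot(tab, ggplot2::aes(x = rtot, y = KD, fill = delta_ec50)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "antigens per cell", y = "KD (M)",
                  fill = "delta EC50")
}
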