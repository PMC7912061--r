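#' Plot a fitted dose-response curve
#'
#' Observed percent inhibition against log-scaled concentration, the
#' fitted (or interpolated) curve, and the IC50 marked at half-maximal
#' inhibition.
#'
#' @param object An `ic50_fit` from [fit_ic50()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ic50_fit <- function(object, ...) {
  obs <- object$data
  grid <- tibble(concentration = 10^seq(log10(min(obs$concentration)),
                                        log10(max(obs$concentration)),
                                        length.out = 200))
  grid$inhibition <- predict(object, grid)
  half <- (object$bottom + object$top) / 2
  ggplot2::ggplot(obs, ggplot2::aes(.data$concentration, .data$inhibition)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = half, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (mg/mL)", y = "inhibition (%)",
      title = sprintf("IC50 = %.4g mg/mL (%s)", object$ic50, object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-motif peptide counts from a pipeline report
#'
#' @param report A `hydrolysate_report` from [run_pipeline()].
#' @return A ggplot bar chart of the number of peptides carrying each
#'   encrypted reference fragment.
#' @export
plot_motif_counts <- function(report) {
  stopifnot(inherits(report, "hydrolysate_report"))
  pm <- report$summary$per_motif
  ggplot2::ggplot(pm, ggplot2::aes(stats::reorder(.data$motif,
                                                  .data$peptide_count),
                                   .data$peptide_count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "peptides containing fragment") +
    ggplot2::theme_minimal()
}
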