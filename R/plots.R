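# ggplot2 views of the three standard comparisons: delineated volumes per
# algorithm, JSI against lesion volume, and ICC distributions per feature
# family.

#' Boxplot of delineated volumes per algorithm
#'
#' @param segmentations Segmentation tibble (e.g. `$segmentations` of
#'   [run_experiment()]), with `algorithm` and `volume_ml` columns.
#' @return A ggplot.
#' @export
plot_volume_comparison <- function(segmentations) {
  ggplot2::ggplot(segmentations,
                  ggplot2::aes(x = .data$algorithm, y = .data$volume_ml)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Delineated volume (ml)",
                  title = "Tumour volume by segmentation algorithm") +
    ggplot2::theme_minimal()
}

#' Scatter of JSI against reference volume with OLS fit
#'
#' @param jsi_with_volume Tibble with `volume_ml`, `jsi_percent` and
#'   `algo_pair` columns.
#' @return A ggplot faceted by algorithm pair, with the least-squares line.
#' @export
plot_jsi_vs_volume <- function(jsi_with_volume) {
  ggplot2::ggplot(jsi_with_volume,
                  ggplot2::aes(x = .data$volume_ml, y = .data$jsi_percent)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linetype = "dashed") +
    ggplot2::facet_wrap(~algo_pair) +
    ggplot2::labs(x = "Reference volume (ml)", y = "JSI (%)",
                  title = "Overlap vs lesion size") +
    ggplot2::theme_minimal()
}

#' Boxplots of ICC by feature family and algorithm
#'
#' @param icc_report ICC tibble from [icc_table()] (columns `feature`,
#'   `algorithm`, `icc`).
#' @return A ggplot with one box per (family, algorithm).
#' @export
plot_icc_by_family <- function(icc_report) {
  dat <- dplyr::inner_join(icc_report, feature_registry(), by = "feature")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$family, y = .data$icc,
                                    fill = .data$algorithm)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = c(0.7, 0.85), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "Inter-reader ICC",
                  title = "Reproducibility by feature family") +
    ggplot2::theme_minimal()
}

#' Forest plot of a survival screen
#'
#' @param x A survival-screen tibble from [run_survival_screen()].
#' @param object,... Unused (autoplot interface).
#' @return A ggplot of per-SD hazard ratios with Wald significance marking.
#' @export
plot_survival_screen <- function(x) {
  ggplot2::ggplot(dplyr::filter(x, !is.na(.data$hr)),
                  ggplot2::aes(x = .data$hr_per_sd, y = .data$feature,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = "Hazard ratio per SD", y = NULL,
                  title = "Univariate Cox screen") +
    ggplot2::theme_minimal()
}
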