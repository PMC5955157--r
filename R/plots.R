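# ggplot2 views of the cohort result tables.

#' Histogram of mean overlap indices per baseline threshold
#'
#' Grouped bar chart of the cohort mean of each overlap index (Dice,
#' Jaccard, OF, VcI, VcR) against the recurrence sub-volume, one group of
#' bars per baseline threshold, with SD error bars.
#'
#' @param overlap_summary A [cohort_overlap_table()] result (or a
#'   `petsubvol_report`, whose `overlap_summary` is used).
#' @return A ggplot object.
#' @export
plot_overlap_indices <- function(overlap_summary) {
  if (inherits(overlap_summary, "petsubvol_report"))
    overlap_summary <- overlap_summary$overlap_summary
  ggplot2::ggplot(overlap_summary,
                  ggplot2::aes(x = .data$i_label, y = .data$mean,
                               fill = .data$index)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 1)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      linewidth = 0.3) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Index") +
    ggplot2::labs(x = "Baseline sub-volume (% of SUVmax)",
                  y = "Mean overlap index") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Mean metabolic sub-volume per threshold
#'
#' @param volume_summary A `petsubvol_report` or its `volume_summary`
#'   tibble.
#' @return A ggplot object (log-scale volumes with SD error bars).
#' @export
plot_volume_thresholds <- function(volume_summary) {
  if (inherits(volume_summary, "petsubvol_report"))
    volume_summary <- volume_summary$volume_summary
  ggplot2::ggplot(volume_summary,
                  ggplot2::aes(x = 100 * .data$fraction, y = .data$mean_cc,
                               color = .data$scan, group = .data$scan)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_cc - .data$sd_cc, 0.01),
                   ymax = .data$mean_cc + .data$sd_cc),
      width = 2, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Threshold (% of SUVmax)",
                  y = "Mean MTV (cc, log scale)", color = "Scan") +
    ggplot2::theme_minimal()
}

#' Autoplot method for cohort reports
#'
#' @param object A `petsubvol_report`.
#' @param type `"overlap"` (default) or `"volumes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.petsubvol_report <- function(object, type = c("overlap", "volumes"),
                                      ...) {
  type <- match.arg(type)
  switch(type,
         overlap = plot_overlap_indices(object),
         volumes = plot_volume_thresholds(object))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
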