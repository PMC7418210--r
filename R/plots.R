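#' Plot p(s) decay curves
#'
#' Log-log contact-fraction curves; pass several samples row-bound to
#' overlay them.
#'
#' @param ps A [ps_curve()] tibble (samples distinguished by `sample`).
#' @return A ggplot object.
#' @export
plot_ps <- function(ps) {
  d <- ps[ps$fraction > 0, ]
  d$mid <- sqrt(d$lower * d$upper)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$fraction,
                                  colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation (bp)", y = "fraction of contacts",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Saddle-plot heatmap
#' @param object A `saddle_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saddle_summary <- function(object, ...) {
  m <- object$matrix
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$oe <- as.vector(t(m))[(d$row - 1) * ncol(m) + d$col]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = log2(.data$oe))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "PC1 rank group", y = "PC1 rank group",
                  fill = "log2 O/E") +
    ggplot2::theme_minimal()
}

#' PC1 compartment profile plot
#' @param object A `compartment_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compartment_profile <- function(object, ...) {
  d <- object[!is.na(object$pc1), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start / 1e6, y = .data$pc1,
                                  fill = .data$label)) +
    ggplot2::geom_col(width = (d$end - d$start) / 1e6) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(A = "#e8a33d", B = "#3d6fe8"),
                               na.value = "grey70") +
    ggplot2::labs(x = "position (Mb)", y = "PC1", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Aggregate boundary insulation profile plot
#' @param profile Tibble from [aggregate_boundary_is()] (add a `sample`
#'   column and row-bind to overlay samples).
#' @return A ggplot object.
#' @export
plot_boundary_profile <- function(profile) {
  aes <- if ("sample" %in% names(profile))
    ggplot2::aes(x = .data$offset / 1e3, y = .data$mean_is, colour = .data$sample)
  else ggplot2::aes(x = .data$offset / 1e3, y = .data$mean_is)
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "offset from boundary (kb)", y = "mean insulation score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' APA / aggregate-TAD panel heatmap
#' @param panel Matrix from [apa()] or [aggregate_tad_signal()].
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  d <- tidyr::expand_grid(row = seq_len(nrow(panel)), col = seq_len(ncol(panel)))
  d$oe <- panel[cbind(d$row, d$col)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$oe)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean O/E") +
    ggplot2::theme_minimal()
}

#' Cumulative domain-size curves
#' @param curves `curves` tibble from [domain_size_curve()].
#' @return A ggplot object.
#' @export
plot_domain_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$relative_size,
                                       y = .data$cumulative_coverage,
                                       colour = .data$sample)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "relative domain size (domain / chromosome length)",
                  y = "cumulative genome coverage", colour = NULL) +
    ggplot2::theme_minimal()
}
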