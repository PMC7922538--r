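#' Plot a handful of spectra
#'
#' Absorbance against the spectral grid for up to `n` samples, colored by a
#' records column (e.g. the contamination class) when supplied.
#'
#' @param spectra A spectra table.
#' @param n Number of spectra to draw (default 20).
#' @param color_by Optional vector aligned with `spectra` (e.g.
#'   `records$true_class`) used for the line color.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, n = 20, color_by = NULL) {
  idx <- seq_len(min(n, nrow(spectra)))
  long <- tidyr::pivot_longer(spectra[idx, ], -"sample_id",
                              names_to = "grid", values_to = "absorbance")
  long$grid <- as.numeric(long$grid)
  if (!is.null(color_by)) {
    key <- tibble::tibble(sample_id = spectra$sample_id, class = color_by)
    long <- dplyr::left_join(long, key, by = "sample_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$grid, .data$absorbance,
                                            group = .data$sample_id,
                                            color = .data$class))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$grid, .data$absorbance,
                                            group = .data$sample_id))
  }
  p + ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "spectral point", y = "absorbance (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a GH distance distribution
#'
#' Histogram of GH values on a log10 x axis with the cleaning limit marked.
#'
#' @param gh GH tibble from [gh_distance()].
#' @param limit GH limit to mark (default 5).
#' @return A ggplot object.
#' @export
plot_gh_distribution <- function(gh, limit = 5) {
  ggplot2::ggplot(gh, ggplot2::aes(.data$gh)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = limit, linetype = 2, color = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "GH distance (log scale)", y = "records") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as a gain versus loss map
#'
#' Each cleaning rule/combination is a point: data loss on x, RMSD gain on
#' y. The parsimony frontier is readable at a glance — rules up and to the
#' left clean more per record discarded.
#'
#' @param object A `mirqc_report` from [evaluate_cleaning()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirqc_report
#' @export
autoplot.mirqc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_loss_pct, .data$gain_pct,
                                       label = .data$rule)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$best_gain | .data$best_ratio),
                        size = 2, show.legend = FALSE) +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey40", "TRUE" = "red")) +
    ggplot2::labs(x = "data loss (%)", y = "RMSD gain (%)",
                  title = unique(object$trait)) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' RMSD gain and data loss against the tested thresholds.
#'
#' @param object A `mirqc_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirqc_sweep
#' @export
autoplot.mirqc_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("gain_pct", "n_loss_pct"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     color = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "threshold", y = "percent", color = NULL,
                  title = sprintf("threshold sweep (%s)", object$trait)) +
    ggplot2::theme_minimal()
}
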