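#' Tidy a calibration projection
#'
#' One row per retained principal component: eigenvalue, proportion of the
#' total calibration spectral variance, and the cumulative proportion.
#'
#' @param x A `calibration_projection`.
#' @param ... Unused.
#' @return A tibble `component`, `eigenvalue`, `prop_variance`,
#'   `cum_variance`.
#' @method tidy calibration_projection
#' @export
tidy.calibration_projection <- function(x, ...) {
  total <- sum(x$eigenvalues) / x$variance_covered
  tibble::tibble(
    component = seq_len(x$n_pc),
    eigenvalue = x$eigenvalues,
    prop_variance = x$eigenvalues / total,
    cum_variance = cumsum(x$eigenvalues) / total
  )
}

#' One-row summary of a calibration projection
#'
#' @param x A `calibration_projection`.
#' @param ... Unused.
#' @return A tibble with `n_pc`, `variance_covered`, `variance_target`,
#'   `n_calibration`, `n_features`, `gap`.
#' @method glance calibration_projection
#' @export
glance.calibration_projection <- function(x, ...) {
  tibble::tibble(
    n_pc = x$n_pc,
    variance_covered = x$variance_covered,
    variance_target = x$variance_target,
    n_calibration = x$n_calibration,
    n_features = length(x$mean_deriv),
    gap = x$gap %||% NA_integer_
  )
}

#' Tidy a surrogate prediction equation
#'
#' @param x A `prediction_equation`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate` (the intercept and each derivative
#'   feature coefficient).
#' @method tidy prediction_equation
#' @export
tidy.prediction_equation <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row summary of a surrogate prediction equation
#'
#' @param x A `prediction_equation`.
#' @param ... Unused.
#' @return A tibble with `trait`, `n_components`, `gap`, `rmse`,
#'   `r_squared`.
#' @method glance prediction_equation
#' @export
glance.prediction_equation <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_components = x$n_components,
                 gap = x$gap, rmse = x$rmse,
                 r_squared = x$r_squared %||% NA_real_)
}

#' Tidy a threshold sweep
#'
#' @param x A `mirqc_sweep`.
#' @param ... Unused.
#' @return The per-threshold table (`threshold`, `n_kept`, `n_loss_pct`,
#'   `rmsd`, `gain_pct`).
#' @method tidy mirqc_sweep
#' @export
tidy.mirqc_sweep <- function(x, ...) x$table

#' One-row summary of a threshold sweep
#'
#' @param x A `mirqc_sweep`.
#' @param ... Unused.
#' @return A tibble with the trait, raw RMSD, number of thresholds, and
#'   the Kruskal-Wallis statistic and p-value.
#' @method glance mirqc_sweep
#' @export
glance.mirqc_sweep <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    rmsd_raw = x$rmsd_raw,
    n_thresholds = nrow(x$table),
    kw_statistic = if (is.null(x$kruskal)) NA_real_ else unname(x$kruskal$statistic),
    kw_p_value = if (is.null(x$kruskal)) NA_real_ else x$kruskal$p.value
  )
}
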