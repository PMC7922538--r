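#' Fit a PCA calibration projection for Global-H scoring
#'
#' Builds the applicability-domain model of a calibration set: a principal
#' component analysis of the (gap-derivative) calibration spectra, keeping
#' the smallest number of components whose cumulative explained variance
#' reaches `variance_target`. The fitted object carries everything needed to
#' score new spectra — the calibration mean spectrum in derivative space,
#' the eigenvectors, and the covariance matrix of the calibration scores —
#' and nothing of the calibration data themselves, so it can be shared by an
#' equation provider without disclosing the calibration set.
#'
#' Principal components with eigenvalue below `1e-10` times the leading
#' eigenvalue are dropped before the covariance is inverted, for numerical
#' stability.
#'
#' @param deriv Derivative feature table from [first_derivative()] (or any
#'   tibble with `sample_id` plus numeric feature columns).
#' @param variance_target Fraction of calibration spectral variance the
#'   retained components must cover (default 0.95).
#' @return An object of class `calibration_projection`: a list with
#'   `mean_deriv`, `rotation` (features x nPC eigenvectors), `score_mean`,
#'   `score_cov` (sample covariance of calibration scores, denominator
#'   n - 1), `eigenvalues`, `n_pc`, `variance_covered`, `n_calibration`,
#'   `gap`, and `feature_names`.
#' @seealso [project_spectra()], [gh_distance()], [write_projection()]
#' @export
fit_calibration_projection <- function(deriv, variance_target = 0.95) {
  if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
    abort("`variance_target` must be in (0, 1].")
  }
  mat <- deriv_matrix(deriv)
  if (nrow(mat) < 3) abort("At least 3 calibration spectra are required.")
  pca <- prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  total <- sum(ev)
  if (total <= 0) abort("Calibration spectra have zero variance; cannot fit a projection.")
  # drop numerically null components before choosing nPC
  ok <- ev >= 1e-10 * ev[1]
  ev <- ev[ok]
  cumvar <- cumsum(ev) / total
  n_pc <- which(cumvar >= variance_target)[1]
  if (is.na(n_pc)) n_pc <- length(ev)
  rotation <- pca$rotation[, seq_len(n_pc), drop = FALSE]
  scores <- pca$x[, seq_len(n_pc), drop = FALSE]
  structure(list(
    mean_deriv = pca$center,
    rotation = rotation,
    score_mean = colMeans(scores),
    score_cov = stats::cov(scores),
    eigenvalues = ev[seq_len(n_pc)],
    n_pc = n_pc,
    variance_covered = cumvar[n_pc],
    variance_target = variance_target,
    n_calibration = nrow(mat),
    gap = attr(deriv, "gap", exact = TRUE),
    feature_names = colnames(mat)
  ), class = "calibration_projection")
}

#' @export
print.calibration_projection <- function(x, ...) {
  cat("<calibration_projection>\n")
  cat(sprintf("  %d components over %d derivative features (gap %s)\n",
              x$n_pc, length(x$mean_deriv),
              if (is.null(x$gap)) "?" else x$gap))
  cat(sprintf("  variance covered: %.2f%% (target %.0f%%), n = %d calibration spectra\n",
              100 * x$variance_covered, 100 * x$variance_target, x$n_calibration))
  invisible(x)
}

#' Project spectra onto a calibration projection
#'
#' Centers derivative spectra on the calibration mean and applies the
#' calibration eigenvectors, yielding the principal-component scores used by
#' [gh_distance()].
#'
#' @param deriv Derivative feature table with the same features as the
#'   projection.
#' @param projection A `calibration_projection`.
#' @return A tibble: `sample_id` plus score columns `PC1..PCk`.
#' @export
project_spectra <- function(deriv, projection) {
  stopifnot(inherits(projection, "calibration_projection"))
  mat <- deriv_matrix(deriv)
  if (ncol(mat) != length(projection$mean_deriv)) {
    abort(sprintf("Spectra have %d derivative features but the projection expects %d.",
                  ncol(mat), length(projection$mean_deriv)))
  }
  scores <- sweep(mat, 2, projection$mean_deriv) %*% projection$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(mat)),
                   tibble::as_tibble(scores))
}

#' Global-H distance of spectra to a calibration centroid
#'
#' The GH applicability-domain score: the squared Mahalanobis distance of a
#' spectrum's principal-component scores to the calibration score centroid,
#' under the covariance of the calibration scores, divided by the number of
#' components. No small-sample `n/(n-1)` inflation factor is applied —
#' calibration sets in this setting are large, so the factor is
#' indistinguishable from 1. A spectrum at the centroid scores 0; large
#' values flag spectra outside the spectral variability the prediction
#' equation was calibrated on.
#'
#' @param scores Score table from [project_spectra()] (or a numeric matrix
#'   of scores with sample ids as row names).
#' @param projection The `calibration_projection` the scores came from.
#' @return A tibble with columns `sample_id` and `gh` (unitless, >= 0); the
#'   number of components used is stored in attribute `"n_pc"`.
#' @examples
#' sp <- new_spectra(matrix(rnorm(50 * 20), 50), paste0("s", 1:50))
#' d <- first_derivative(sp, gap = 2)
#' pr <- fit_calibration_projection(d, 0.95)
#' gh <- gh_distance(project_spectra(d, pr), pr)
#' mean(gh$gh)   # (n - 1) / n for the calibration spectra themselves
#' @export
gh_distance <- function(scores, projection) {
  stopifnot(inherits(projection, "calibration_projection"))
  if (is.data.frame(scores)) {
    ids <- as.character(scores$sample_id)
    mat <- as.matrix(scores[setdiff(names(scores), "sample_id")])
  } else {
    mat <- as.matrix(scores)
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  S <- projection$score_cov
  if (ncol(mat) != ncol(S)) {
    abort(sprintf("Scores have %d components but the projection uses %d.",
                  ncol(mat), ncol(S)))
  }
  kap <- kappa(S, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    abort(paste("Score covariance is near-singular (condition number >",
                "1e12); refit with a lower `variance_target`."))
  }
  h2 <- mahalanobis(mat, center = projection$score_mean, cov = S)
  out <- tibble::tibble(sample_id = ids, gh = as.numeric(h2) / projection$n_pc)
  attr(out, "n_pc") <- projection$n_pc
  out
}

#' Compute GH scores for raw spectra in one step
#'
#' Convenience wrapper: gap derivative, projection, and [gh_distance()].
#'
#' @param spectra A spectra table on the grid the projection was fitted to.
#' @param projection A `calibration_projection` (its stored `gap` is used).
#' @return GH tibble as from [gh_distance()].
#' @export
compute_gh <- function(spectra, projection) {
  gap <- projection$gap %||% 5
  deriv <- first_derivative(spectra, gap = gap)
  gh_distance(project_spectra(deriv, projection), projection)
}
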