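#' Piecewise standardization coefficients
#'
#' Inter-instrument spectral standardization is applied as precomputed
#' piecewise linear maps: every spectral point whose position index falls in
#' segment `[start, end]` is transformed as `slope * x + intercept`.
#' Segments must tile the grid: contiguous, non-overlapping, covering every
#' point. Estimating the coefficients (an inter-laboratory exercise on shared
#' samples) is out of scope; this package only applies them.
#'
#' @param start,end Integer position indices (1-based, inclusive) of each
#'   segment on the spectral grid.
#' @param slope,intercept Numeric coefficients per segment.
#' @return A tibble with columns `start`, `end`, `slope`, `intercept`,
#'   ordered by `start`.
#' @examples
#' standardization_segments(c(1, 5), c(4, 9), c(1, 1.02), c(0, -0.001))
#' @export
standardization_segments <- function(start, end, slope, intercept) {
  seg <- tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    slope = as.numeric(slope), intercept = as.numeric(intercept)
  )
  seg <- dplyr::arrange(seg, .data$start)
  if (any(seg$end < seg$start)) abort("Segment `end` must be >= `start`.")
  if (!all(is.finite(seg$slope)) || !all(is.finite(seg$intercept))) {
    abort("Segment slopes and intercepts must be finite.")
  }
  if (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)] + 1)) {
    abort("Segments must be contiguous and non-overlapping.")
  }
  seg
}

#' Apply piecewise standardization to spectra
#'
#' @param spectra A spectra table (see [new_spectra()]).
#' @param segments Segment table from [standardization_segments()]; must
#'   start at point 1 and end at the last spectral point.
#' @return A spectra table on the same grid with each absorbance `x`
#'   replaced by `slope * x + intercept` of its segment.
#' @export
apply_standardization <- function(spectra, segments) {
  mat <- spectra_matrix(spectra)
  grid <- spectra_grid(spectra)
  segments <- standardization_segments(segments$start, segments$end,
                                       segments$slope, segments$intercept)
  if (segments$start[1] != 1L || segments$end[nrow(segments)] != ncol(mat)) {
    abort(sprintf(
      "Segments cover points %d..%d but the spectra have points 1..%d.",
      segments$start[1], segments$end[nrow(segments)], ncol(mat)))
  }
  for (i in seq_len(nrow(segments))) {
    idx <- segments$start[i]:segments$end[i]
    mat[, idx] <- segments$slope[i] * mat[, idx] + segments$intercept[i]
  }
  new_spectra(mat, rownames(mat), grid)
}

#' Gap first derivative of spectra
#'
#' The classic chemometric gap derivative used to remove baseline drift
#' before PCA: `d[i] = a[i + gap] - a[i]`, unnormalized, shortening each
#' spectrum by `gap` points. Any constant offset added to a spectrum
#' vanishes, and the operator is linear.
#'
#' @param spectra A spectra table.
#' @param gap Integer gap (default 5), strictly less than the number of
#'   spectral points.
#' @return A tibble of derivative features (`sample_id` plus
#'   `n_points - gap` columns named `d<grid>` after the left point of each
#'   difference), with the gap stored in attribute `"gap"`.
#' @examples
#' sp <- new_spectra(matrix(1:10, 1), "a")   # linear ramp
#' first_derivative(sp, gap = 3)             # every feature equals 3
#' @export
first_derivative <- function(spectra, gap = 5) {
  gap <- as.integer(gap)
  mat <- spectra_matrix(spectra)
  grid <- spectra_grid(spectra)
  if (gap < 1L) abort("`gap` must be >= 1.")
  if (gap >= ncol(mat)) {
    abort(sprintf("`gap` (%d) must be smaller than the number of spectral points (%d).",
                  gap, ncol(mat)))
  }
  keep <- seq_len(ncol(mat) - gap)
  d <- mat[, keep + gap, drop = FALSE] - mat[, keep, drop = FALSE]
  colnames(d) <- paste0("d", format_grid(grid[keep]))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(mat)),
                          tibble::as_tibble(d))
  attr(out, "gap") <- gap
  out
}

deriv_matrix <- function(deriv) {
  mat <- as.matrix(deriv[setdiff(names(deriv), "sample_id")])
  rownames(mat) <- as.character(deriv$sample_id)
  mat
}
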