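#' Build a spectra table
#'
#' A spectra table is the package's wide representation of a set of MIR
#' spectra: a tibble whose first column is `sample_id` and whose remaining
#' columns are absorbance values at the spectral points named by the grid
#' (indices or wavenumbers, strictly increasing).
#'
#' @param absorbance Numeric matrix, samples in rows, spectral points in
#'   columns.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `absorbance`.
#' @param grid Numeric vector of spectral-point positions (defaults to
#'   `1:ncol(absorbance)`), strictly increasing.
#' @return A tibble with `nrow(absorbance)` rows: `sample_id` plus one
#'   numeric column per grid point.
#' @examples
#' sp <- new_spectra(matrix(rnorm(12), 3), c("a", "b", "c"))
#' spectra_grid(sp)
#' @export
new_spectra <- function(absorbance, sample_ids, grid = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.null(grid)) grid <- seq_len(ncol(absorbance))
  validate_grid(grid, ncol(absorbance))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    abort("`sample_ids` must have one entry per spectrum row.")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample id: ",
                 sample_ids[duplicated(sample_ids)][1]))
  }
  if (anyNA(absorbance) || !is.numeric(absorbance)) {
    abort("Absorbance values must be numeric with no missing values.")
  }
  colnames(absorbance) <- format_grid(grid)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                   tibble::as_tibble(absorbance))
}

format_grid <- function(grid) format(grid, trim = TRUE, scientific = FALSE)

validate_grid <- function(grid, n_points) {
  if (length(grid) != n_points) {
    abort("Grid length must equal the number of spectral points.")
  }
  if (anyNA(grid) || any(diff(grid) <= 0)) {
    abort("Grid must be strictly increasing with no missing values.")
  }
  invisible(grid)
}

#' Validate a data frame as a spectra table
#'
#' Checks the layout produced by [new_spectra()] / [read_spectra()]:
#' `sample_id` first, unique ids, numeric complete absorbances, strictly
#' increasing grid parsed from the column names.
#'
#' @param x A data frame.
#' @return `x` as a validated tibble.
#' @export
as_spectra <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) abort("Spectra need a `sample_id` column.")
  x <- dplyr::relocate(x, "sample_id")
  ids <- as.character(x$sample_id)
  mat <- spectra_matrix(x)
  new_spectra(mat, ids, spectra_grid(x))
}

#' Extract the absorbance matrix from a spectra table
#'
#' @param x A spectra table.
#' @return Numeric matrix (samples x points) with sample ids as row names.
#' @export
spectra_matrix <- function(x) {
  cols <- setdiff(names(x), "sample_id")
  mat <- as.matrix(x[cols])
  if (!is.numeric(mat)) abort("Spectra contain non-numeric absorbance cells.")
  if (anyNA(mat)) abort("Spectra contain missing absorbance values.")
  rownames(mat) <- as.character(x$sample_id)
  mat
}

#' Extract the spectral grid from a spectra table
#'
#' @param x A spectra table.
#' @return Numeric vector of grid positions parsed from the column names.
#' @export
spectra_grid <- function(x) {
  g <- suppressWarnings(as.numeric(setdiff(names(x), "sample_id")))
  if (anyNA(g)) abort("Spectral column names must be numeric grid positions.")
  validate_grid(g, length(g))
}
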