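#' Read spectra from a wide CSV file
#'
#' Expected layout: header row whose first field is `sample_id` and whose
#' remaining fields are numeric grid positions; one row per sample with the
#' absorbances. Duplicate ids and non-numeric cells are rejected.
#'
#' @param path CSV file path.
#' @return A validated spectra table.
#' @export
read_spectra <- function(path) {
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      .default = readr::col_double())))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed spectra file %s: e.g. line %d, %s.",
                  path, prob$row[1] + 1, prob$expected[1]))
  }
  as_spectra(df)
}

#' Write spectra to a wide CSV file
#'
#' @param spectra A spectra table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  readr::write_csv(as_spectra(spectra), path)
  invisible(path)
}

#' Read a phenotype records table
#'
#' @param path CSV file path.
#' @param traits Character vector of traits that must be present as
#'   `INT_<trait>` and `EXT_<trait>` columns.
#' @return A validated records tibble (`days_in_milk` and
#'   `lactation_number` coerced to integer when present).
#' @export
read_records <- function(path, traits = "fat") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c(paste0("INT_", traits), paste0("EXT_", traits))
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("Records file lacks required trait column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"sample_id" %in% names(df)) abort("Records need a `sample_id` column.")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("Duplicate sample id: ",
                 df$sample_id[duplicated(df$sample_id)][1]))
  }
  for (col in c("days_in_milk", "lactation_number")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  tibble::as_tibble(df)
}

#' Write a phenotype records table
#'
#' @param records Records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Serialize a calibration projection to JSON
#'
#' Stores exactly what GH scoring needs — the calibration mean derivative
#' spectrum, the eigenvectors, the score covariance — plus metadata
#' (`n_pc`, gap, variance target, calibration size) and a format-version
#' field. None of the calibration spectra themselves are stored, so the
#' file can be circulated by an equation provider.
#'
#' @param projection A `calibration_projection`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(projection, path) {
  stopifnot(inherits(projection, "calibration_projection"))
  payload <- list(
    format = "mirqc_calibration_projection",
    version = 1L,
    n_pc = projection$n_pc,
    variance_covered = projection$variance_covered,
    variance_target = projection$variance_target,
    n_calibration = projection$n_calibration,
    gap = projection$gap,
    feature_names = projection$feature_names,
    mean_deriv = unname(projection$mean_deriv),
    score_mean = unname(projection$score_mean),
    eigenvalues = unname(projection$eigenvalues),
    rotation = unname(projection$rotation),
    score_cov = unname(projection$score_cov)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a calibration projection from JSON
#'
#' @param path A file written by [write_projection()].
#' @return A `calibration_projection`.
#' @export
read_projection <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "mirqc_calibration_projection")) {
    abort(sprintf("%s is not a mirqc calibration projection file.", path))
  }
  rotation <- matrix(unlist(p$rotation), ncol = p$n_pc)
  rownames(rotation) <- p$feature_names
  structure(list(
    mean_deriv = setNames(as.numeric(p$mean_deriv), p$feature_names),
    rotation = rotation,
    score_mean = as.numeric(p$score_mean),
    score_cov = matrix(unlist(p$score_cov), p$n_pc, p$n_pc),
    eigenvalues = as.numeric(p$eigenvalues),
    n_pc = as.integer(p$n_pc),
    variance_covered = p$variance_covered,
    variance_target = p$variance_target,
    n_calibration = as.integer(p$n_calibration),
    gap = if (is.null(p$gap)) NULL else as.integer(p$gap),
    feature_names = p$feature_names
  ), class = "calibration_projection")
}

#' Write a cleaning mask to CSV
#'
#' @param mask A cleaning mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  readr::write_csv(mask, path)
  invisible(path)
}
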