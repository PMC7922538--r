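#' Cleaning-rule thresholds
#'
#' Bundle of the default thresholds used by the record-cleaning rules:
#' extreme-quantile bounds for the quantile rule (M1), the GH limit for the
#' applicability-domain rule (M2), the absolute fat-residual limit for the
#' residual rule (M3), and the plausibility prefilter bounds (ICAR-style
#' ranges for fat and protein plus the days-in-milk window).
#'
#' @param m1_p_low,m1_p_high Quantile probabilities for M1 (defaults 0.01,
#'   0.99).
#' @param m2_gh_limit GH limit for M2 (default 5, unitless).
#' @param m3_fat_limit Absolute fat-residual limit for M3 (default 0.30
#'   g/dL).
#' @param fat_range,protein_range Closed plausibility intervals in g/dL
#'   (defaults `c(1.5, 9.0)` and `c(1.0, 7.0)`).
#' @param dim_range Closed days-in-milk interval (default `c(5, 365)`).
#' @return A list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(m1_p_low = 0.01, m1_p_high = 0.99,
                            m2_gh_limit = 5, m3_fat_limit = 0.30,
                            fat_range = c(1.5, 9.0),
                            protein_range = c(1.0, 7.0),
                            dim_range = c(5, 365)) {
  if (m1_p_low >= m1_p_high) abort("`m1_p_low` must be < `m1_p_high`.")
  if (m2_gh_limit <= 0 || m3_fat_limit <= 0) abort("Rule limits must be > 0.")
  structure(list(m1_p_low = m1_p_low, m1_p_high = m1_p_high,
                 m2_gh_limit = m2_gh_limit, m3_fat_limit = m3_fat_limit,
                 fat_range = fat_range, protein_range = protein_range,
                 dim_range = dim_range),
            class = "rule_thresholds")
}

new_cleaning_mask <- function(sample_ids, flagged, rule) {
  if (!nzchar(rule)) abort("Mask provenance (`rule`) must be non-empty.")
  tibble::tibble(sample_id = as.character(sample_ids),
                 flagged = as.logical(flagged),
                 rule = rule)
}

mask_ids_aligned <- function(masks) {
  ids <- lapply(masks, function(m) as.character(m$sample_id))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    abort("Masks cover different sample ids; align them before combining.")
  }
  ids[[1]]
}

#' Plausibility prefilter on fat, protein and days in milk
#'
#' Flags records whose internal fat or protein content falls outside the
#' closed plausibility ranges, or whose days in milk lies outside the
#' recording window. Records exactly on a bound are kept. Columns
#' `INT_fat` / `INT_protein` are used when present, else `fat` / `protein`.
#'
#' @param records A records tibble.
#' @param thresholds A [rule_thresholds()].
#' @return A cleaning mask: tibble `sample_id`, `flagged`, `rule`.
#' @export
icar_prefilter <- function(records, thresholds = rule_thresholds()) {
  pick <- function(primary, fallback) {
    if (primary %in% names(records)) records[[primary]]
    else if (fallback %in% names(records)) records[[fallback]]
    else abort(sprintf("Prefilter needs a `%s` (or `%s`) column.", primary, fallback))
  }
  fat <- pick("INT_fat", "fat")
  protein <- pick("INT_protein", "protein")
  if (!"days_in_milk" %in% names(records)) {
    abort("Prefilter needs a `days_in_milk` column.")
  }
  dim_ <- records$days_in_milk
  out_of <- function(x, r) x < r[1] | x > r[2]
  flagged <- out_of(fat, thresholds$fat_range) |
    out_of(protein, thresholds$protein_range) |
    out_of(dim_, thresholds$dim_range)
  rule <- sprintf("prefilter[fat %g-%g, protein %g-%g, dim %g-%g]",
                  thresholds$fat_range[1], thresholds$fat_range[2],
                  thresholds$protein_range[1], thresholds$protein_range[2],
                  thresholds$dim_range[1], thresholds$dim_range[2])
  new_cleaning_mask(records$sample_id, flagged, rule)
}

#' Extreme-quantile rule (M1)
#'
#' Flags records whose externally predicted value for the trait under study
#' falls strictly below the lower or strictly above the upper empirical
#' quantile of that trait (linear-interpolation quantiles; equality with a
#' threshold keeps the record). In routine use the thresholds are computed
#' once on the full post-prefilter dataset and then treated as fixed;
#' supply them via `fixed_thresholds` when combining with other rules on a
#' subset.
#'
#' @param records Records tibble with an `EXT_<trait>` column (or pass the
#'   column name via `col`).
#' @param trait Trait under study (default `"fat"`).
#' @param thresholds A [rule_thresholds()] supplying the quantile
#'   probabilities.
#' @param fixed_thresholds Optional numeric `c(low, high)` overriding the
#'   empirical quantiles.
#' @param col Column to screen (default `paste0("EXT_", trait)`).
#' @return A cleaning mask with the thresholds used recorded in the `rule`
#'   string and in attribute `"thresholds"`.
#' @export
m1_quantile_rule <- function(records, trait = "fat",
                             thresholds = rule_thresholds(),
                             fixed_thresholds = NULL,
                             col = paste0("EXT_", trait)) {
  if (!col %in% names(records)) {
    abort(sprintf("Column `%s` not found for the quantile rule.", col))
  }
  values <- records[[col]]
  if (is.null(fixed_thresholds)) {
    if (length(values) < 100) {
      warn("Fewer than 100 values: empirical 1%/99% quantiles are unstable.")
    }
    q <- unname(quantile(values, c(thresholds$m1_p_low, thresholds$m1_p_high),
                         names = FALSE, type = 7))
  } else {
    q <- as.numeric(fixed_thresholds)
  }
  if (q[1] == q[2]) {
    warn("Quantile thresholds coincide (constant values?); nothing flagged.")
  }
  flagged <- values < q[1] | values > q[2]
  rule <- sprintf("M1[%s < %.6g | > %.6g]", col, q[1], q[2])
  out <- new_cleaning_mask(records$sample_id, flagged, rule)
  attr(out, "thresholds") <- q
  out
}

#' GH applicability-domain rule (M2)
#'
#' Flags records whose GH distance exceeds the limit (strictly; a record at
#' the limit is kept). Large GH values identify spectra outside the
#' spectral variability of the calibration set behind the trait's
#' prediction equation.
#'
#' @param gh A GH tibble from [gh_distance()] / [compute_gh()], or any data
#'   frame with `sample_id` and the column named by `gh_col`.
#' @param limit GH limit (default 5).
#' @param gh_col Name of the GH column (default `"gh"`).
#' @return A cleaning mask.
#' @export
m2_gh_rule <- function(gh, limit = 5, gh_col = "gh") {
  if (!gh_col %in% names(gh)) {
    abort(sprintf("Column `%s` with GH values not found.", gh_col))
  }
  new_cleaning_mask(gh$sample_id, gh[[gh_col]] > limit,
                    sprintf("M2[GH > %g]", limit))
}

#' Absolute fat-residual rule (M3)
#'
#' Flags records whose absolute difference between the externally predicted
#' and the internal (slope/bias-corrected, hence assumed-control) fat
#' content exceeds the limit (strictly; equality keeps the record). Large
#' fat residuals indicate poor-quality spectra or a wrong sample/record
#' association, whatever trait is being studied.
#'
#' @param records Records tibble with `INT_fat` and `EXT_fat` columns.
#' @param limit Absolute residual limit in g/dL (default 0.30).
#' @return A cleaning mask.
#' @export
m3_fat_residual_rule <- function(records, limit = 0.30) {
  if (!all(c("INT_fat", "EXT_fat") %in% names(records))) {
    abort("The fat-residual rule needs `INT_fat` and `EXT_fat` columns.")
  }
  resid <- abs(records$EXT_fat - records$INT_fat)
  new_cleaning_mask(records$sample_id, resid > limit,
                    sprintf("M3[|EXT_fat - INT_fat| > %g]", limit))
}

#' Combine cleaning masks
#'
#' `mode = "or"` flags a record flagged by any input rule (union: delete
#' whatever any rule finds suspicious); `mode = "and"` flags only records
#' flagged by every input rule (intersection: delete only records extreme
#' by all rules at once, the parsimonious choice).
#'
#' @param masks List of cleaning masks over identical sample ids.
#' @param mode `"and"` or `"or"`.
#' @return A cleaning mask with concatenated provenance.
#' @examples
#' a <- mirqc:::new_cleaning_mask(c("1", "2", "3"), c(TRUE, FALSE, FALSE), "A")
#' b <- mirqc:::new_cleaning_mask(c("1", "2", "3"), c(FALSE, TRUE, FALSE), "B")
#' combine_masks(list(a, b), "or")$flagged   # TRUE TRUE FALSE
#' combine_masks(list(a, b), "and")$flagged  # FALSE FALSE FALSE
#' @export
combine_masks <- function(masks, mode = c("or", "and")) {
  mode <- match.arg(mode)
  if (!length(masks)) abort("At least one mask is required.")
  ids <- mask_ids_aligned(masks)
  flags <- vapply(masks, function(m) m$flagged, logical(length(ids)))
  flags <- matrix(flags, nrow = length(ids))
  flagged <- if (mode == "or") rowSums(flags) > 0 else rowSums(flags) == ncol(flags)
  prov <- paste(vapply(masks, function(m) m$rule[1], character(1)),
                collapse = sprintf(" %s ", mode))
  new_cleaning_mask(ids, flagged, sprintf("(%s)", prov))
}

#' Apply a cleaning mask to a records table
#'
#' @param records Records tibble.
#' @param mask Cleaning mask over the same sample ids.
#' @param quiet Suppress the retained/removed message (default TRUE).
#' @return The records restricted to unflagged rows; the input is never
#'   modified.
#' @export
apply_mask <- function(records, mask, quiet = TRUE) {
  if (!identical(as.character(records$sample_id), as.character(mask$sample_id))) {
    abort("Mask and records cover different sample ids.")
  }
  kept <- records[!mask$flagged, , drop = FALSE]
  if (!quiet) {
    message(sprintf("%s: removed %d of %d records (%d kept)",
                    mask$rule[1], sum(mask$flagged), nrow(records), nrow(kept)))
  }
  kept
}
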