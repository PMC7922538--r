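#' Root mean square difference between external and internal predictions
#'
#' `sqrt(mean((ext - int_)^2))` — the agreement statistic between the
#' externally predicted and the manufacturer's (internal) phenotype values,
#' in g/dL.
#'
#' @param ext,int_ Numeric vectors of equal, positive length.
#' @return The RMSD (>= 0).
#' @examples
#' rmsd(c(3, 4), c(0, 0))  # sqrt(25 / 2)
#' @export
rmsd <- function(ext, int_) {
  if (length(ext) != length(int_)) abort("`ext` and `int_` must have equal length.")
  if (length(ext) == 0) abort("RMSD of zero records is undefined.")
  sqrt(mean((ext - int_)^2))
}

#' RMSD gain of a cleaning rule
#'
#' Percentage improvement of the RMSD achieved by cleaning, expressed
#' relative to the post-cleaning RMSD: `(before / after - 1) * 100`. A rule
#' that halves the RMSD therefore gains 100%.
#'
#' @param rmsd_before,rmsd_after RMSD before and after cleaning (> 0).
#' @return Gain in percent.
#' @export
rmsd_gain <- function(rmsd_before, rmsd_after) {
  if (any(rmsd_before <= 0)) abort("`rmsd_before` must be > 0.")
  if (any(rmsd_after <= 0)) {
    abort("`rmsd_after` is 0: the gain is undefined (division by the post-cleaning RMSD).")
  }
  (rmsd_before / rmsd_after - 1) * 100
}

#' Data loss of a cleaning mask
#'
#' @param mask A cleaning mask.
#' @return Percentage of records flagged for deletion.
#' @export
data_loss <- function(mask) {
  if (nrow(mask) == 0) abort("Cannot compute data loss of an empty mask.")
  100 * mean(mask$flagged)
}

#' Gain-to-loss ratio
#'
#' The parsimony criterion for comparing cleaning rules: RMSD gain (%)
#' divided by data loss (%).
#'
#' @param gain_pct,n_loss_pct Gain and loss percentages; the loss must be
#'   positive.
#' @return Unitless ratio.
#' @examples
#' gain_loss_ratio(38.82, 8.88)  # ~ 4.37
#' @export
gain_loss_ratio <- function(gain_pct, n_loss_pct) {
  if (any(n_loss_pct <= 0)) {
    abort("Gain:loss is undefined when the data loss is 0.")
  }
  gain_pct / n_loss_pct
}

#' Descriptive statistics of a predicted phenotype
#'
#' Mean, SD (sample, n - 1), CV (`100 * SD / mean`), range, and the
#' population (biased) standardized central-moment skewness and kurtosis.
#' Kurtosis is reported as excess kurtosis by default (0 for a normal
#' distribution); `kurtosis = "raw"` reports the unshifted fourth
#' standardized moment (3 for a normal distribution).
#'
#' @param values Numeric vector (n >= 2 for the SD, n >= 4 for kurtosis).
#' @param kurtosis `"excess"` (default) or `"raw"`.
#' @return A one-row tibble: `n`, `mean`, `sd`, `cv`, `min`, `max`,
#'   `skewness`, `kurtosis`. For constant input the SD is 0 and the shape
#'   statistics are `NA`.
#' @export
descriptive_stats <- function(values, kurtosis = c("excess", "raw")) {
  kurtosis <- match.arg(kurtosis)
  n <- length(values)
  if (n < 2) abort("At least 2 values are needed for descriptive statistics.")
  m <- mean(values)
  s <- sd(values)
  m2 <- mean((values - m)^2)
  skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else NA_real_
  kurt <- if (n >= 4 && m2 > 0) {
    k <- mean((values - m)^4) / m2^2
    if (kurtosis == "excess") k - 3 else k
  } else {
    NA_real_
  }
  tibble::tibble(
    n = n, mean = m, sd = s,
    cv = if (m > 0) 100 * s / m else NA_real_,
    min = min(values), max = max(values),
    skewness = skew, kurtosis = kurt
  )
}

#' Correlation between GH distance and squared prediction differences
#'
#' Pearson correlation of the GH distances with the squared differences
#' between external and internal predictions — the strength of the linear
#' link between spectral extrapolation and prediction disagreement.
#'
#' @param gh GH tibble from [gh_distance()] or a numeric vector.
#' @param ext,int_ External and internal predictions aligned with `gh`.
#' @return Pearson r, or `NA` (with a warning) if either side has zero
#'   variance.
#' @export
gh_error_correlation <- function(gh, ext, int_) {
  g <- if (is.data.frame(gh)) gh$gh else as.numeric(gh)
  if (length(g) != length(ext) || length(ext) != length(int_)) {
    abort("`gh`, `ext` and `int_` must be aligned.")
  }
  if (length(g) < 3) abort("At least 3 records are needed for a correlation.")
  e2 <- (ext - int_)^2
  if (sd(g) == 0 || sd(e2) == 0) {
    warn("Zero variance in GH or squared differences; correlation undefined.")
    return(NA_real_)
  }
  cor(g, e2)
}

#' Sweep a cleaning threshold and rank-test the squared differences
#'
#' For each threshold, records with `statistic_values` strictly above the
#' threshold are removed and the kept set's RMSD, gain over the raw RMSD,
#' and data loss are recorded. The squared external-internal differences of
#' the kept sets are then compared across thresholds with a Kruskal-Wallis
#' omnibus rank test and pairwise two-sample Wilcoxon rank-sum tests
#' (tie-corrected normal approximation; unadjusted p-values by default).
#'
#' @param records Records tibble with `INT_<trait>` and `EXT_<trait>`.
#' @param statistic_values Per-record screening statistic aligned with
#'   `records` (e.g. GH distances, or absolute fat residuals).
#' @param thresholds Numeric vector (>= 2) of limits to test.
#' @param trait Trait under study (default `"fat"`).
#' @param p_adjust `"none"` (default) or `"bonferroni"` for the pairwise
#'   p-values.
#' @return An object of class `mirqc_sweep`: list with `table` (one row per
#'   threshold: `threshold`, `n_kept`, `n_loss_pct`, `rmsd`, `gain_pct`),
#'   `kruskal` (htest), `pairwise` (p-value matrix), `trait`.
#' @export
threshold_sweep <- function(records, statistic_values, thresholds,
                            trait = "fat", p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (length(thresholds) < 2) abort("At least 2 thresholds are required.")
  thresholds <- sort(thresholds)
  ext <- records[[paste0("EXT_", trait)]]
  int_ <- records[[paste0("INT_", trait)]]
  if (is.null(ext) || is.null(int_)) {
    abort(sprintf("Records lack INT_%s / EXT_%s columns.", trait, trait))
  }
  if (length(statistic_values) != nrow(records)) {
    abort("`statistic_values` must align with `records`.")
  }
  e2 <- (ext - int_)^2
  rmsd_raw <- sqrt(mean(e2))
  kept_sets <- lapply(thresholds, function(th) which(statistic_values <= th))
  tab <- purrr::map2_dfr(thresholds, kept_sets, function(th, idx) {
    if (!length(idx)) {
      return(tibble::tibble(threshold = th, n_kept = 0L, n_loss_pct = 100,
                            rmsd = NA_real_, gain_pct = NA_real_))
    }
    r <- sqrt(mean(e2[idx]))
    tibble::tibble(threshold = th, n_kept = length(idx),
                   n_loss_pct = 100 * (1 - length(idx) / nrow(records)),
                   rmsd = r,
                   gain_pct = if (r > 0) (rmsd_raw / r - 1) * 100 else NA_real_)
  })
  nonempty <- which(lengths(kept_sets) > 0)
  kw <- if (length(nonempty) >= 2) {
    kruskal.test(
      x = unlist(lapply(kept_sets[nonempty], function(idx) e2[idx])),
      g = factor(rep(thresholds[nonempty], lengths(kept_sets[nonempty])))
    )
  } else {
    NULL
  }
  k <- length(thresholds)
  pw <- matrix(NA_real_, k, k, dimnames = list(thresholds, thresholds))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- kept_sets[[i]]; b <- kept_sets[[j]]
      if (length(a) && length(b)) {
        pw[i, j] <- pw[j, i] <- suppressWarnings(
          wilcox.test(e2[a], e2[b], exact = FALSE, correct = TRUE)$p.value)
      }
    }
  }
  if (p_adjust == "bonferroni") {
    n_comp <- sum(!is.na(pw[upper.tri(pw)]))
    pw <- pmin(pw * n_comp, 1)
  }
  structure(list(table = tab, kruskal = kw, pairwise = pw, trait = trait,
                 rmsd_raw = rmsd_raw),
            class = "mirqc_sweep")
}

#' @export
print.mirqc_sweep <- function(x, ...) {
  cat(sprintf("<mirqc_sweep> trait '%s', raw RMSD %.4g g/dL\n", x$trait, x$rmsd_raw))
  print(x$table)
  if (!is.null(x$kruskal)) {
    cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.3g\n",
                unname(x$kruskal$statistic), unname(x$kruskal$parameter),
                x$kruskal$p.value))
  }
  invisible(x)
}

#' Overlap between the records discarded by different rules
#'
#' For each ordered pair of masks (A, B), the percentage of A's flagged
#' records also flagged by B: `100 * |A & B| / |A|`.
#'
#' @param masks Named list of cleaning masks over identical sample ids.
#' @return A tibble `rule_a`, `rule_b`, `n_a`, `overlap_pct` (NA when A
#'   flags nothing), for all ordered pairs.
#' @export
method_overlap <- function(masks) {
  if (is.null(names(masks)) || any(!nzchar(names(masks)))) {
    abort("`masks` must be a named list.")
  }
  mask_ids_aligned(masks)
  pairs <- expand.grid(rule_a = names(masks), rule_b = names(masks),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$rule_a != pairs$rule_b, ]
  purrr::pmap_dfr(pairs, function(rule_a, rule_b) {
    a <- masks[[rule_a]]$flagged
    b <- masks[[rule_b]]$flagged
    tibble::tibble(
      rule_a = rule_a, rule_b = rule_b, n_a = sum(a),
      overlap_pct = if (sum(a) == 0) NA_real_ else 100 * sum(a & b) / sum(a)
    )
  })
}

#' Evaluate the three cleaning rules and all their combinations
#'
#' Builds the quantile (M1), GH (M2) and fat-residual (M3) masks for one
#' trait, combines them with `and` / `or` over both pairs and the triple,
#' and reports for each of the 11 rules the RMSD before and after cleaning,
#' the RMSD gain, the data loss and the gain:loss ratio, plus the SD of the
#' external predictions and the internal-external correlation after
#' cleaning. M1 thresholds are computed once on the full table and treated
#' as fixed.
#'
#' @param records Records tibble with `INT_fat` / `EXT_fat`,
#'   `INT_<trait>` / `EXT_<trait>`, and a GH column for the trait.
#' @param trait Trait under study (default `"fat"`).
#' @param gh_col Column with the trait's GH distances (default
#'   `paste0("GH_", trait)`).
#' @param thresholds A [rule_thresholds()].
#' @return A tibble of class `mirqc_report`: one row per rule with columns
#'   `trait`, `rule`, `n_before`, `n_after`, `rmsd_before`, `rmsd_after`,
#'   `gain_pct`, `n_loss_pct`, `gain_loss_ratio`, `sd_after`, `r_after`,
#'   `best_gain`, `best_ratio`.
#' @export
evaluate_cleaning <- function(records, trait = "fat",
                              gh_col = paste0("GH_", trait),
                              thresholds = rule_thresholds()) {
  if (!gh_col %in% names(records)) {
    abort(sprintf("Records lack the GH column `%s`; compute GH first.", gh_col))
  }
  m1 <- m1_quantile_rule(records, trait, thresholds)
  m2 <- m2_gh_rule(records, limit = thresholds$m2_gh_limit, gh_col = gh_col)
  m3 <- m3_fat_residual_rule(records, limit = thresholds$m3_fat_limit)
  base <- list(M1 = m1, M2 = m2, M3 = m3)
  combos <- list(
    "M1 and M2" = combine_masks(base[c("M1", "M2")], "and"),
    "M1 and M3" = combine_masks(base[c("M1", "M3")], "and"),
    "M2 and M3" = combine_masks(base[c("M2", "M3")], "and"),
    "M1 and M2 and M3" = combine_masks(base, "and"),
    "M1 or M2" = combine_masks(base[c("M1", "M2")], "or"),
    "M1 or M3" = combine_masks(base[c("M1", "M3")], "or"),
    "M2 or M3" = combine_masks(base[c("M2", "M3")], "or"),
    "M1 or M2 or M3" = combine_masks(base, "or")
  )
  all_masks <- c(base, combos)
  ext <- records[[paste0("EXT_", trait)]]
  int_ <- records[[paste0("INT_", trait)]]
  before <- rmsd(ext, int_)
  rows <- purrr::imap_dfr(all_masks, function(mask, rule) {
    keep <- !mask$flagged
    after <- if (any(keep)) rmsd(ext[keep], int_[keep]) else NA_real_
    loss <- data_loss(mask)
    gain <- if (!is.na(after) && after > 0) rmsd_gain(before, after) else NA_real_
    tibble::tibble(
      trait = trait, rule = rule,
      n_before = nrow(records), n_after = sum(keep),
      rmsd_before = before, rmsd_after = after,
      gain_pct = gain, n_loss_pct = loss,
      gain_loss_ratio = ifelse(loss > 0, gain / loss, NA_real_),
      sd_after = if (sum(keep) >= 2) sd(ext[keep]) else NA_real_,
      r_after = if (sum(keep) >= 3) cor(ext[keep], int_[keep]) else NA_real_
    )
  })
  rows$best_gain <- !is.na(rows$gain_pct) &
    rows$gain_pct == max(rows$gain_pct, na.rm = TRUE)
  rows$best_ratio <- !is.na(rows$gain_loss_ratio) &
    rows$gain_loss_ratio == max(rows$gain_loss_ratio, na.rm = TRUE)
  class(rows) <- c("mirqc_report", class(rows))
  attr(rows, "masks") <- all_masks
  rows
}
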