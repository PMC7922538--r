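test_that("the plausibility prefilter keeps closed-interval boundaries", {
  rec <- tibble::tibble(
    sample_id = as.character(1:6),
    INT_fat = c(5.0, 5.0, 9.01, 9.00, 1.49, 1.5),
    INT_protein = c(3.4, 3.4, 3.4, 3.4, 3.4, 7.01),
    days_in_milk = c(100, 4, 100, 365, 100, 100)
  )
  mask <- icar_prefilter(rec)
  expect_identical(mask$flagged, c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(icar_prefilter(rec[, 1:3]), "days_in_milk")
  expect_error(icar_prefilter(tibble::tibble(sample_id = "1",
                                             days_in_milk = 10)), "fat")
})

test_that("the quantile rule flags about 2% of continuous data and keeps ties", {
  set.seed(10)
  rec <- tibble::tibble(sample_id = as.character(1:10000),
                        EXT_fat = rnorm(10000, 4, 1))
  mask <- m1_quantile_rule(rec, "fat")
  frac <- mean(mask$flagged)
  expect_gte(frac, 0.015)
  expect_lte(frac, 0.025)

  # equality with a threshold keeps the record
  q <- attr(mask, "thresholds")
  fixed <- m1_quantile_rule(rec, "fat", fixed_thresholds = q)
  at_bound <- tibble::tibble(sample_id = "x", EXT_fat = q[2])
  expect_false(m1_quantile_rule(at_bound, "fat", fixed_thresholds = q)$flagged)
  expect_true(m1_quantile_rule(
    tibble::tibble(sample_id = "x", EXT_fat = q[2] + 1e-9),
    "fat", fixed_thresholds = q)$flagged)
  expect_identical(fixed$flagged, mask$flagged)
})

test_that("the quantile rule warns on constant or tiny inputs", {
  const <- tibble::tibble(sample_id = as.character(1:200), EXT_fat = 3.3)
  expect_warning(mask <- m1_quantile_rule(const, "fat"), "coincide")
  expect_false(any(mask$flagged))
  small <- tibble::tibble(sample_id = as.character(1:10), EXT_fat = rnorm(10))
  expect_warning(m1_quantile_rule(small, "fat"), "100")
  expect_error(m1_quantile_rule(const, "protein"), "EXT_protein")
})

test_that("the GH rule flags strictly above the limit", {
  gh <- tibble::tibble(sample_id = as.character(1:4),
                       gh = c(0, 4.99, 5.0, 5.01))
  mask <- m2_gh_rule(gh, limit = 5)
  expect_identical(mask$flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(m2_gh_rule(gh, gh_col = "GH_fat"), "GH_fat")
})

test_that("the GH rule's flagged fraction matches the chi-square tail", {
  set.seed(77)
  n_pc <- 10
  gh <- tibble::tibble(sample_id = as.character(1:50000),
                       gh = rchisq(50000, n_pc) / n_pc)
  frac <- mean(m2_gh_rule(gh, limit = 2)$flagged)
  want <- 1 - pchisq(2 * n_pc, n_pc)   # 0.0293
  expect_lt(abs(frac - want), 3 * sqrt(want * (1 - want) / 50000))
})

test_that("the fat-residual rule flags strictly above the limit", {
  rec <- tibble::tibble(
    sample_id = as.character(1:4),
    INT_fat = c(4, 4, 4, 4),
    EXT_fat = c(4, 4.30, 4.31, 3.69)
  )
  mask <- m3_fat_residual_rule(rec, limit = 0.30)
  expect_identical(mask$flagged, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(m3_fat_residual_rule(rec[, 1:2]), "EXT_fat")
})

test_that("mask combination follows set algebra", {
  ids <- as.character(1:3)
  a <- mask_of(ids, "1", "A")
  b <- mask_of(ids, "2", "B")
  expect_identical(combine_masks(list(a, b), "and")$flagged, rep(FALSE, 3))
  expect_identical(combine_masks(list(a, b), "or")$flagged,
                   c(TRUE, TRUE, FALSE))
  # idempotence
  expect_identical(combine_masks(list(a, a), "and")$flagged, a$flagged)
  expect_identical(combine_masks(list(a, a), "or")$flagged, a$flagged)
  expect_error(combine_masks(list(a, mask_of(c("9", "2", "3"), "2"))),
               "different sample ids")
})

test_that("combinators satisfy De Morgan on every 2-mask pattern", {
  # exhaustive over all flag patterns of two masks on two records
  ids <- c("r1", "r2")
  patterns <- expand.grid(a1 = c(TRUE, FALSE), a2 = c(TRUE, FALSE),
                          b1 = c(TRUE, FALSE), b2 = c(TRUE, FALSE))
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    a <- mirqc:::new_cleaning_mask(ids, c(p$a1, p$a2), "A")
    b <- mirqc:::new_cleaning_mask(ids, c(p$b1, p$b2), "B")
    or_flag <- combine_masks(list(a, b), "or")$flagged
    and_kept_complement <- !combine_masks(
      list(mirqc:::new_cleaning_mask(ids, !a$flagged, "notA"),
           mirqc:::new_cleaning_mask(ids, !b$flagged, "notB")), "and")$flagged
    expect_identical(or_flag, and_kept_complement)
  }
})

test_that("or-losses bound inputs from above and and-losses from below", {
  set.seed(4)
  ids <- as.character(1:500)
  masks <- lapply(1:3, function(j) {
    mirqc:::new_cleaning_mask(ids, runif(500) < 0.2, paste0("R", j))
  })
  fracs <- vapply(masks, function(m) mean(m$flagged), numeric(1))
  expect_gte(mean(combine_masks(masks, "or")$flagged), max(fracs))
  expect_lte(mean(combine_masks(masks, "and")$flagged), min(fracs))
})

test_that("apply_mask restricts rows and preserves schema", {
  rec <- make_records(n = 5)
  none <- mask_of(rec$sample_id, character(0))
  expect_identical(apply_mask(rec, none), rec)

  all_mask <- mask_of(rec$sample_id, rec$sample_id)
  empty <- apply_mask(rec, all_mask)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(rec))

  two <- mask_of(rec$sample_id, rec$sample_id[c(2, 4)])
  kept <- apply_mask(rec, two)
  expect_identical(kept$sample_id, rec$sample_id[c(1, 3, 5)])
  expect_error(apply_mask(rec[5:1, ], two), "different sample ids")
})

test_that("fixed-threshold rules are idempotent; the quantile rule is not", {
  rec <- make_records(n = 2000, fat_resid_sd = 0.2)
  rec$GH_fat <- rchisq(2000, 9) / 9

  for (mask in list(m2_gh_rule(rec, 2, "GH_fat"),
                    m3_fat_residual_rule(rec, 0.30),
                    icar_prefilter(rec))) {
    cleaned <- apply_mask(rec, mask)
    again <- switch(substr(mask$rule[1], 1, 2),
                    "M2" = m2_gh_rule(cleaned, 2, "GH_fat"),
                    "M3" = m3_fat_residual_rule(cleaned, 0.30),
                    icar_prefilter(cleaned))
    expect_identical(sum(again$flagged), 0L, info = mask$rule[1])
  }

  # M1 recomputes its quantiles, so reapplication flags afresh
  m1 <- m1_quantile_rule(rec, "fat")
  cleaned <- apply_mask(rec, m1)
  expect_gt(sum(m1_quantile_rule(cleaned, "fat")$flagged), 0)
})

test_that("raising a threshold never increases the flagged count", {
  rec <- make_records(n = 1000, fat_resid_sd = 0.3)
  rec$GH_fat <- rchisq(1000, 9) / 9

  gh_counts <- vapply(c(1, 2, 4, 8),
                      function(l) sum(m2_gh_rule(rec, l, "GH_fat")$flagged),
                      integer(1))
  expect_true(all(diff(gh_counts) <= 0))

  fat_counts <- vapply(c(0.08, 0.1, 0.3, 0.4),
                       function(l) sum(m3_fat_residual_rule(rec, l)$flagged),
                       integer(1))
  expect_true(all(diff(fat_counts) <= 0))

  m1_counts <- vapply(c(0.01, 0.02, 0.05), function(p) {
    sum(m1_quantile_rule(rec, "fat",
                         rule_thresholds(m1_p_low = p, m1_p_high = 1 - p))$flagged)
  }, integer(1))
  expect_true(all(diff(rev(m1_counts)) <= 0))
})
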