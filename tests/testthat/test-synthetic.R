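test_that("configuration validation catches bad inputs", {
  expect_s3_class(small_cfg(), "mirqc_config")
  expect_error(small_cfg(calib_size = 0), "positive")
  expect_error(small_cfg(contamination = c(clean = 0.8, extrapolated = 0.1,
                                           degraded = 0.05, mismatched = 0.1)),
               "sum to 1")
  expect_error(small_cfg(contamination = c(clean = 1, bad = 0)), "exactly")
  expect_error(small_cfg(spectral_noise_sd = -1), ">= 0")
  expect_error(small_cfg(trait_defs = tibble::tibble(x = 1)), "trait")
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- small_cfg(seed = 42)
  a <- generate_calibration_set(cfg, "fat")
  b <- generate_calibration_set(cfg, "fat")
  expect_identical(a, b)

  eq <- build_prediction_equation(a$spectra, a$values, trait = "fat",
                                  n_components = 4)
  f1 <- generate_field_records(cfg, list(fat = eq, protein = eq))
  f2 <- generate_field_records(cfg, list(fat = eq, protein = eq))
  expect_identical(f1, f2)

  # a different seed changes the draws
  expect_false(identical(
    a$values$value,
    generate_calibration_set(small_cfg(seed = 43), "fat")$values$value))
})

test_that("zero-amplitude, zero-noise spectra collapse to the mean curve", {
  cfg <- noiseless_cfg(latent_amplitude = 0, n_latent = 1)
  cal <- generate_calibration_set(cfg, "fat")
  mat <- spectra_matrix(cal$spectra)
  expect_equal(unname(mat),
               matrix(mirqc:::latent_model(cfg)$mean_curve,
                      nrow(mat), ncol(mat), byrow = TRUE))
})

test_that("calibration trait moments recover the configured mean and SD", {
  cfg <- small_cfg(calib_size = 2000, trait_defs = tibble::tibble(
    trait = "fat", mean = 3.93, sd = 1.00))
  val <- generate_calibration_set(cfg, "fat")$values$value
  se_mean <- 1.00 / sqrt(2000)
  se_sd <- 1.00 / sqrt(2 * 2000)
  expect_lt(abs(mean(val) - 3.93), 3 * se_mean)
  expect_lt(abs(sd(val) - 1.00), 3 * se_sd)
})

test_that("surrogate equations recover a noiseless linear trait exactly", {
  cfg <- noiseless_cfg()
  cal <- generate_calibration_set(cfg, "fat")
  eq <- build_prediction_equation(cal$spectra, cal$values, trait = "fat",
                                  n_components = cfg$n_latent)
  expect_lte(eq$rmse, 1e-8)
  pred <- predict(eq, cal$spectra)
  expect_equal(pred$value, cal$values$value, tolerance = 1e-8)
})

test_that("constant trait values give a zero equation", {
  cfg <- small_cfg()
  cal <- generate_calibration_set(cfg, "fat")
  eq <- build_prediction_equation(cal$spectra, rep(2.5, cfg$calib_size),
                                  trait = "fat")
  expect_equal(unname(eq$coefficients), rep(0, 120 - 5))
  expect_equal(eq$intercept, 2.5)
  expect_equal(predict(eq, cal$spectra)$value, rep(2.5, cfg$calib_size))
})

test_that("study-scale surrogate equations are highly accurate in-sample", {
  pop <- acceptance_population()
  expect_gt(pop$equation$r_squared, 0.97)
})

test_that("equation fitting validates rank and sample size", {
  cfg <- small_cfg()
  cal <- generate_calibration_set(cfg, "fat")
  expect_error(build_prediction_equation(cal$spectra[1:6, ],
                                         cal$values$value[1:6],
                                         n_components = 8),
               "n_components")
  flat <- new_spectra(matrix(1:10, 12, 10, byrow = TRUE),
                      sprintf("f%02d", 1:12))
  expect_error(build_prediction_equation(flat, rnorm(12), n_components = 5),
               "rank")
})

test_that("internal predictions apply slope, bias and instrument noise", {
  expect_equal(simulate_internal_prediction(c(1, 2, 3), 0), c(1, 2, 3))
  expect_equal(simulate_internal_prediction(4.00, 0, slope = 1.02, bias = -0.05),
               4.03)
  int <- simulate_internal_prediction(rep(3, 10000), noise_sd = 0.05,
                                      slope = 1.02, bias = -0.05, seed = 99)
  resid <- int - 1.02 * 3 + 0.05
  expect_lt(abs(sd(resid) - 0.05 * 1.02), 0.05 * 0.05 * 1.02)
  expect_error(simulate_internal_prediction(1, -0.1), ">= 0")
})

test_that("an all-clean noiseless population has EXT equal to INT", {
  cfg <- noiseless_cfg(contamination = c(clean = 1, extrapolated = 0,
                                         degraded = 0, mismatched = 0))
  cal <- generate_calibration_set(cfg, "fat")
  eqs <- lapply(c(fat = "fat", protein = "protein"), function(tr) {
    c2 <- generate_calibration_set(cfg, tr)
    build_prediction_equation(c2$spectra, c2$values, trait = tr,
                              n_components = cfg$n_latent)
  })
  fld <- generate_field_records(cfg, eqs)
  expect_equal(rmsd(fld$records$EXT_fat, fld$records$INT_fat), 0,
               tolerance = 1e-7)
  expect_equal(rmsd(fld$records$EXT_protein, fld$records$INT_protein), 0,
               tolerance = 1e-7)
})

test_that("field generation requires an equation per configured trait", {
  cfg <- small_cfg()
  cal <- generate_calibration_set(cfg, "fat")
  eq <- build_prediction_equation(cal$spectra, cal$values, trait = "fat",
                                  n_components = 4)
  expect_error(generate_field_records(cfg, list(fat = eq)), "protein")
})

test_that("contamination classes behave as designed", {
  cfg <- small_cfg(field_size = 1500,
                   trait_defs = default_trait_defs()[1, ])
  cal <- generate_calibration_set(cfg, "fat")
  eq <- build_prediction_equation(cal$spectra, cal$values, trait = "fat",
                                  n_components = 4)
  fld <- generate_field_records(cfg, list(fat = eq))
  rec <- fld$records
  expect_setequal(unique(rec$true_class),
                  c("clean", "extrapolated", "degraded", "mismatched"))

  resid <- abs(rec$EXT_fat - rec$INT_fat)
  expect_gt(mean(resid[rec$true_class == "degraded"]),
            mean(resid[rec$true_class == "clean"]))
  expect_gt(mean(resid[rec$true_class == "mismatched"]),
            mean(resid[rec$true_class == "clean"]))

  # mismatched records carry another record's spectrum but their own truth
  mis <- which(rec$true_class == "mismatched")
  mat <- spectra_matrix(fld$spectra)
  donors <- vapply(mis, function(i) {
    any(apply(mat[-i, , drop = FALSE], 1, function(r) all(r == mat[i, ])))
  }, logical(1))
  expect_true(all(donors))

  # GH separation of extrapolated records, computed downstream
  proj <- fit_calibration_projection(first_derivative(cal$spectra, gap = 5))
  gh <- compute_gh(fld$spectra, proj)
  expect_gt(mean(gh$gh[rec$true_class == "extrapolated"]),
            mean(gh$gh[rec$true_class == "clean"]))
})

test_that("record metadata is plausible and ids unique", {
  cfg <- small_cfg()
  cal <- generate_calibration_set(cfg, "fat")
  eq <- build_prediction_equation(cal$spectra, cal$values, trait = "fat",
                                  n_components = 4)
  rec <- generate_field_records(cfg, list(fat = eq, protein = eq))$records
  expect_false(anyDuplicated(rec$sample_id) > 0)
  expect_true(all(rec$days_in_milk >= 5 & rec$days_in_milk <= 365))
  expect_true(all(rec$lactation_number >= 1 & rec$lactation_number <= 13))
  expect_true(all(c("true_fat", "INT_fat", "EXT_fat",
                    "true_protein", "INT_protein", "EXT_protein") %in% names(rec)))
})
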