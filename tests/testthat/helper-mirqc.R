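# Small synthetic configuration for fast mechanical tests. Dimensions are
# deliberately modest; statistical behaviour at study scale is exercised in
# test-acceptance.R.
small_cfg <- function(...) {
  args <- list(n_wavelengths = 120, n_latent = 4, calib_size = 250,
               field_size = 400, trait_defs = default_trait_defs()[1:2, ],
               seed = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# Noise-free configuration: trait exactly linear in the latent factors,
# internal prediction equal to the truth.
noiseless_cfg <- function(...) {
  args <- list(spectral_noise_sd = 0, trait_noise_sd = 0,
               instrument_noise_sd = 0, slope = 1, bias = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(small_cfg, args)
}

# Random spectra table for operator tests.
random_spectra <- function(n = 10, p = 30, seed = 42) {
  set.seed(seed)
  new_spectra(matrix(rnorm(n * p), n, p), sprintf("s%03d", seq_len(n)))
}

# Minimal records table with aligned ids.
make_records <- function(n = 120, seed = 7, fat_resid_sd = 0.05) {
  set.seed(seed)
  fat <- rnorm(n, 3.9, 1.1)
  protein <- rnorm(n, 3.4, 0.4)
  tibble::tibble(
    sample_id = sprintf("r%04d", seq_len(n)),
    days_in_milk = sample(5:365, n, replace = TRUE),
    INT_fat = fat,
    EXT_fat = fat + rnorm(n, 0, fat_resid_sd),
    INT_protein = protein,
    EXT_protein = protein + rnorm(n, 0, fat_resid_sd)
  )
}

mask_of <- function(ids, flagged_ids, rule = "test") {
  mirqc:::new_cleaning_mask(ids, ids %in% flagged_ids, rule)
}

# The study-scale contaminated population used by the acceptance suite:
# built once per test run at the package default seed and cached.
acceptance_env <- new.env(parent = emptyenv())
acceptance_population <- function() {
  if (!is.null(acceptance_env$pop)) {
    return(acceptance_env$pop)
  }
  cfg <- synthetic_config(
    trait_defs = default_trait_defs()[default_trait_defs()$trait == "fat", ],
    field_size = 20000, seed = 1
  )
  cal <- generate_calibration_set(cfg, "fat")
  eq <- build_prediction_equation(cal$spectra, cal$values, trait = "fat")
  proj <- fit_calibration_projection(first_derivative(cal$spectra, gap = 5))
  fld <- generate_field_records(cfg, list(fat = eq))
  rec <- fld$records
  rec$GH_fat <- compute_gh(fld$spectra, proj)$gh
  acceptance_env$pop <- list(cfg = cfg, calibration = cal, equation = eq,
                             projection = proj, records = rec)
  acceptance_env$pop
}
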