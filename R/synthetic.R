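#' Default trait definitions
#'
#' Trait means and standard deviations (g/dL of milk) used by the synthetic
#' generator: fat, protein, monounsaturated (MFA), saturated (SFA) and
#' unsaturated (UFA) fatty acids, at the location/scale typical of
#' spectrometer-predicted values in large Holstein milk-recording
#' populations.
#'
#' @return A tibble with columns `trait`, `mean`, `sd`.
#' @export
default_trait_defs <- function() {
  tibble::tibble(
    trait = c("fat", "protein", "mfa", "sfa", "ufa"),
    mean  = c(3.93, 3.41, 0.85, 2.58, 0.92),
    sd    = c(1.10, 0.42, 0.32, 0.76, 0.38)
  )
}

#' Configuration for the synthetic MIR population
#'
#' Defines every knob of the latent-factor generative model used to emulate
#' a milk MIR prediction pipeline: spectra are a smooth mean absorbance
#' curve plus a low-rank smooth latent structure plus white noise, and each
#' trait is a linear combination of the latent factors plus measurement
#' noise, rescaled to the configured mean and SD. Field populations mix four
#' record classes: `clean`, `extrapolated` (minor latent directions drawn
#' with inflated SD plus a systematic shift along the two least-calibrated
#' ones — out-of-calibration spectral variability at plausible trait
#' values),
#' `degraded` (clean spectrum plus heavy white noise of random severity and
#' a random baseline offset — poor-quality spectra) and `mismatched` (the
#' record keeps its own internal values while its spectrum is swapped with
#' another record's — sample/record association errors).
#'
#' @param n_wavelengths Number of spectral points (default 899).
#' @param n_latent Number of latent spectral factors (default 10).
#' @param calib_size Calibration-set size (default 1800).
#' @param field_size Field-population size (default 20000).
#' @param trait_defs Tibble with `trait`, `mean`, `sd` (g/dL); defaults to
#'   [default_trait_defs()].
#' @param contamination Named fractions for classes `clean`, `extrapolated`,
#'   `degraded`, `mismatched`; must each lie in `[0, 1]` and sum to 1.
#' @param latent_amplitude Spectrum-space amplitude of the leading latent
#'   loading (absorbance units, default 0.03); 0 gives flat spectra equal to
#'   the mean curve.
#' @param spectral_noise_sd SD of the white absorbance noise on clean
#'   spectra (default 5e-4).
#' @param trait_noise_sd SD of trait measurement noise in latent units
#'   (default 0.015).
#' @param instrument_noise_sd SD (g/dL) of the spectrometer's internal
#'   prediction noise (default 0.01).
#' @param slope,bias Ring-test style slope/bias correction pair applied to
#'   internal predictions (defaults 1 and 0).
#' @param extrapolation_shift Multiplier on the SD of the upper half of
#'   the latent scores for extrapolated records (default 3.5).
#' @param extrapolation_mean_shift Size, in latent SDs, of the random-sign
#'   mean shift applied to the last two latent factors of extrapolated
#'   records (default 6).
#' @param degraded_severity_range Range of the per-record severity of the
#'   smooth random spectral artifact (baseline wiggle / band distortion)
#'   added to degraded spectra, as a multiple of the leading latent loading
#'   amplitude (default `c(0.5, 3)`). Smooth artifacts both corrupt the
#'   external prediction and inflate GH, as poor-quality spectra do; white
#'   noise alone would be largely cancelled by the gap derivative.
#' @param degraded_baseline_range Range of the uniform flat baseline offset
#'   added to degraded spectra (default `c(-0.1, 0.1)`); removed exactly by
#'   the gap derivative, so degradation is detected through the artifact,
#'   not the offset.
#' @param seed Master integer seed. Every downstream draw uses a named child
#'   stream derived from it, so changing one contamination fraction does not
#'   perturb the draws of the other classes.
#' @return A validated list of class `mirqc_config`.
#' @examples
#' cfg <- synthetic_config(field_size = 500, seed = 7)
#' @export
synthetic_config <- function(n_wavelengths = 899,
                             n_latent = 10,
                             calib_size = 1800,
                             field_size = 20000,
                             trait_defs = default_trait_defs(),
                             contamination = c(clean = 0.90, extrapolated = 0.05,
                                               degraded = 0.03, mismatched = 0.02),
                             latent_amplitude = 0.03,
                             spectral_noise_sd = 5e-4,
                             trait_noise_sd = 0.015,
                             instrument_noise_sd = 0.01,
                             slope = 1,
                             bias = 0,
                             extrapolation_shift = 3.5,
                             extrapolation_mean_shift = 6,
                             degraded_severity_range = c(0.5, 3),
                             degraded_baseline_range = c(-0.1, 0.1),
                             seed = 1L) {
  counts <- c(n_wavelengths = n_wavelengths, n_latent = n_latent,
              calib_size = calib_size, field_size = field_size)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("All counts (n_wavelengths, n_latent, calib_size, field_size) must be positive integers.")
  }
  trait_defs <- tibble::as_tibble(trait_defs)
  if (!all(c("trait", "mean", "sd") %in% names(trait_defs)) || nrow(trait_defs) < 1) {
    abort("`trait_defs` needs columns trait, mean, sd and at least one row.")
  }
  classes <- c("clean", "extrapolated", "degraded", "mismatched")
  if (!setequal(names(contamination), classes)) {
    abort("`contamination` must name exactly: clean, extrapolated, degraded, mismatched.")
  }
  contamination <- contamination[classes]
  if (any(contamination < 0) || any(contamination > 1) ||
      abs(sum(contamination) - 1) > 1e-8) {
    abort("Contamination fractions must lie in [0, 1] and sum to 1.")
  }
  sds <- c(latent_amplitude, spectral_noise_sd, trait_noise_sd,
           instrument_noise_sd, trait_defs$sd)
  if (any(sds < 0)) abort("All SDs and amplitudes must be >= 0.")
  structure(list(
    n_wavelengths = as.integer(n_wavelengths),
    n_latent = as.integer(n_latent),
    calib_size = as.integer(calib_size),
    field_size = as.integer(field_size),
    trait_defs = trait_defs,
    contamination = contamination,
    latent_amplitude = latent_amplitude,
    spectral_noise_sd = spectral_noise_sd,
    trait_noise_sd = trait_noise_sd,
    instrument_noise_sd = instrument_noise_sd,
    slope = slope,
    bias = bias,
    extrapolation_shift = extrapolation_shift,
    extrapolation_mean_shift = extrapolation_mean_shift,
    degraded_severity_range = degraded_severity_range,
    degraded_baseline_range = degraded_baseline_range,
    seed = as.integer(seed)
  ), class = "mirqc_config")
}

#' @export
print.mirqc_config <- function(x, ...) {
  cat("<mirqc_config>\n")
  cat(sprintf("  %d spectral points, %d latent factors, calibration n = %d, field n = %d\n",
              x$n_wavelengths, x$n_latent, x$calib_size, x$field_size))
  cat(sprintf("  traits: %s\n", paste(x$trait_defs$trait, collapse = ", ")))
  cat(sprintf("  contamination: %s\n",
              paste(sprintf("%s %.0f%%", names(x$contamination),
                            100 * x$contamination), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic (seed-free) latent spectral model: smooth mean absorbance
# curve, smooth sinusoidal loadings orthogonal across factors with
# geometrically decaying derivative-space energy (0.85^(k-1)), and a
# geometrically decaying trait link beta_k = 0.6^(k-1).
latent_model <- function(cfg) {
  t <- seq(0, 1, length.out = cfg$n_wavelengths)
  mean_curve <- 0.4 +
    0.8 * exp(-((t - 0.28) / 0.10)^2) +
    0.5 * exp(-((t - 0.62) / 0.15)^2) +
    0.3 * exp(-((t - 0.85) / 0.05)^2)
  k <- seq_len(cfg$n_latent)
  freq <- k + 3
  # distinct integer frequencies keep the loadings (and their gap
  # derivatives) mutually orthogonal; amplitude ~ 1/freq makes the
  # derivative-space energy decay as 0.85^(k-1)
  amp <- cfg$latent_amplitude * 0.85^(k - 1) * (freq[1] / freq)
  loadings <- sapply(k, function(j) amp[j] * sin(2 * pi * freq[j] * t))
  loadings <- matrix(loadings, nrow = cfg$n_wavelengths)
  list(mean_curve = mean_curve, loadings = loadings, beta = 0.6^(k - 1))
}

# Smooth random artifacts for degraded spectra: pink-weighted random
# Fourier series (frequencies 1..30, coefficient SD ~ severity / frequency)
# spanning and exceeding the latent frequency band. Uses the current RNG
# stream of the calling class block.
degraded_artifacts <- function(cfg, m, severity) {
  t <- seq(0, 1, length.out = cfg$n_wavelengths)
  freqs <- 1:30
  amp0 <- cfg$latent_amplitude * 4
  basis_sin <- sapply(freqs, function(f) sin(2 * pi * f * t))
  basis_cos <- sapply(freqs, function(f) cos(2 * pi * f * t))
  scale <- amp0 / (freqs * sqrt(2))
  a <- matrix(rnorm(m * length(freqs)), m) * rep(scale, each = m) * severity
  b <- matrix(rnorm(m * length(freqs)), m) * rep(scale, each = m) * severity
  tcrossprod(a, basis_sin) + tcrossprod(b, basis_cos)
}

# Trait values from latent scores: linear link plus measurement noise,
# rescaled to the configured (mean, sd) using the theoretical raw SD.
trait_from_latent <- function(z, beta, trait_mean, trait_sd, noise_sd, n) {
  raw <- as.numeric(z %*% beta) + rnorm(n, 0, noise_sd)
  scale <- sqrt(sum(beta^2) + noise_sd^2)
  trait_mean + trait_sd * raw / scale
}

#' Generate a synthetic calibration set
#'
#' Draws `calib_size` clean spectra (mean curve + smooth low-rank latent
#' structure + white noise) together with the true contents of one trait,
#' for use with [build_prediction_equation()] and
#' [fit_calibration_projection()]. Deterministic for a fixed config seed;
#' each trait uses its own random stream, so calibration sets differ across
#' traits as they do across real prediction equations.
#'
#' @param cfg A [synthetic_config()].
#' @param trait Trait name present in `cfg$trait_defs`.
#' @return A list with `spectra` (spectra table) and `values` (tibble
#'   `sample_id`, `value` in g/dL).
#' @export
generate_calibration_set <- function(cfg, trait = cfg$trait_defs$trait[1]) {
  stopifnot(inherits(cfg, "mirqc_config"))
  def <- cfg$trait_defs[cfg$trait_defs$trait == trait, ]
  if (nrow(def) != 1) abort(sprintf("Trait '%s' is not in `cfg$trait_defs`.", trait))
  model <- latent_model(cfg)
  n <- cfg$calib_size
  with_seed(child_seed(cfg$seed, paste0("calibration-", trait)), {
    z <- matrix(rnorm(n * cfg$n_latent), n, cfg$n_latent)
    eps <- matrix(rnorm(n * cfg$n_wavelengths, 0, cfg$spectral_noise_sd),
                  n, cfg$n_wavelengths)
    absorb <- tcrossprod(z, model$loadings) + eps
    absorb <- sweep(absorb, 2, model$mean_curve, "+")
    values <- trait_from_latent(z, model$beta, def$mean, def$sd,
                                cfg$trait_noise_sd, n)
    ids <- sprintf("cal_%s_%05d", trait, seq_len(n))
    list(spectra = new_spectra(absorb, ids),
         values = tibble::tibble(sample_id = ids, value = values))
  })
}

#' Fit a surrogate prediction equation
#'
#' Principal component regression of a trait on the gap-derivative spectra
#' of a calibration set: the trait is regressed on the first `n_components`
#' PC scores and the fit is folded back to a single coefficient vector over
#' derivative features. This stands in for the proprietary external
#' prediction equations of real pipelines; it is plumbing that makes the
#' quality-assurance pipeline runnable, not a calibration methodology.
#'
#' @param spectra Calibration spectra table.
#' @param values Numeric trait values, or a tibble with `sample_id` and
#'   `value` aligned with `spectra`.
#' @param trait Trait name stored on the equation.
#' @param gap Derivative gap (default 5).
#' @param n_components Number of PC scores in the regression (default 8).
#' @return An object of class `prediction_equation`: `trait`, `intercept`,
#'   `coefficients` (over derivative features), `gap`, `n_wavelengths`,
#'   `n_components`, in-sample `rmse` and `r_squared`.
#' @export
build_prediction_equation <- function(spectra, values, trait = "trait",
                                      gap = 5, n_components = 8) {
  if (is.data.frame(values)) {
    stopifnot(identical(as.character(values$sample_id),
                        as.character(spectra$sample_id)))
    values <- values$value
  }
  mat <- spectra_matrix(spectra)
  if (length(values) != nrow(mat)) abort("One trait value per spectrum is required.")
  if (nrow(mat) < n_components + 2) {
    abort(sprintf("Need at least n_components + 2 = %d samples, got %d.",
                  n_components + 2, nrow(mat)))
  }
  deriv <- first_derivative(spectra, gap = gap)
  x <- deriv_matrix(deriv)
  eq_skeleton <- function(coefs, intercept, rmse, r2) {
    structure(list(trait = trait, intercept = intercept,
                   coefficients = setNames(as.numeric(coefs), colnames(x)),
                   gap = as.integer(gap), n_wavelengths = ncol(mat),
                   n_components = as.integer(n_components),
                   rmse = rmse, r_squared = r2),
              class = "prediction_equation")
  }
  if (sd(values) == 0) {
    return(eq_skeleton(rep(0, ncol(x)), values[1], 0, NA_real_))
  }
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  if (ev[1] <= .Machine$double.eps || sum(ev >= 1e-12 * ev[1]) < n_components) {
    abort(sprintf(
      "Derivative spectra have numerical rank < %d; cannot fit %d components.",
      n_components, n_components))
  }
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  fit <- lm(values ~ scores)
  b <- coef(fit)
  coefs <- pca$rotation[, seq_len(n_components), drop = FALSE] %*% b[-1]
  intercept <- b[[1]] - sum(pca$center * coefs)
  fitted <- as.numeric(x %*% coefs + intercept)
  rmse <- sqrt(mean((values - fitted)^2))
  r2 <- 1 - sum((values - fitted)^2) / sum((values - mean(values))^2)
  eq_skeleton(coefs, intercept, rmse, r2)
}

#' @export
print.prediction_equation <- function(x, ...) {
  cat(sprintf("<prediction_equation> trait '%s': %d PC components, gap %d\n",
              x$trait, x$n_components, x$gap))
  cat(sprintf("  in-sample RMSE %.4g g/dL, R^2 %.4f\n", x$rmse,
              x$r_squared %||% NA_real_))
  invisible(x)
}

#' Predict a trait from spectra with a surrogate equation
#'
#' @param object A `prediction_equation`.
#' @param spectra A spectra table on the grid the equation was built for.
#' @param ... Unused.
#' @return A tibble with `sample_id` and predicted `value` (g/dL).
#' @export
predict.prediction_equation <- function(object, spectra, ...) {
  mat <- spectra_matrix(spectra)
  if (ncol(mat) != object$n_wavelengths) {
    abort(sprintf("Equation expects %d spectral points, got %d.",
                  object$n_wavelengths, ncol(mat)))
  }
  x <- deriv_matrix(first_derivative(spectra, gap = object$gap))
  tibble::tibble(sample_id = rownames(mat),
                 value = as.numeric(x %*% object$coefficients + object$intercept))
}

#' Simulate the spectrometer's internal prediction
#'
#' The internal (manufacturer) value as milk laboratories report it: the
#' true content plus instrument noise, passed through the slope/bias
#' correction estimated from ring tests — `INT = slope * (true + noise) +
#' bias`.
#'
#' @param true_values True contents (g/dL).
#' @param noise_sd Instrument noise SD (g/dL, >= 0).
#' @param slope,bias Ring-test correction pair.
#' @param seed Optional integer seed; when supplied the draw is made in an
#'   isolated RNG stream.
#' @return Numeric vector of internal predictions.
#' @examples
#' simulate_internal_prediction(4, 0, slope = 1.02, bias = -0.05)  # 4.03
#' @export
simulate_internal_prediction <- function(true_values, noise_sd = 0.02,
                                         slope = 1, bias = 0, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  draw <- function() slope * (true_values + rnorm(length(true_values), 0, noise_sd)) + bias
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a contaminated synthetic field population
#'
#' Draws `cfg$field_size` milk records with per-record contamination class
#' (`clean`, `extrapolated`, `degraded`, `mismatched`, drawn with the
#' configured fractions), builds their spectra, computes external
#' predictions by applying the supplied equations to each record's possibly
#' corrupted spectrum, and internal predictions from each record's own true
#' values via [simulate_internal_prediction()]. Mismatched records keep
#' their truth-based internal values while their spectrum (hence their
#' external value) comes from another, uniformly drawn, record —
#' reproducing a wrong sample/record association. Each class and stage uses
#' its own child RNG stream of `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param equations Named list of `prediction_equation`s covering every
#'   trait in `cfg$trait_defs`.
#' @return A list with `spectra` (spectra table of the final, possibly
#'   corrupted, spectra) and `records`: a tibble with `sample_id`,
#'   `cow_id`, `days_in_milk`, `lactation_number`, `true_class`, and per
#'   trait `true_<trait>`, `INT_<trait>`, `EXT_<trait>` (g/dL).
#' @export
generate_field_records <- function(cfg, equations) {
  stopifnot(inherits(cfg, "mirqc_config"))
  traits <- cfg$trait_defs$trait
  missing <- setdiff(traits, names(equations))
  if (length(missing)) {
    abort(paste0("No prediction equation supplied for trait(s): ",
                 paste(missing, collapse = ", ")))
  }
  model <- latent_model(cfg)
  n <- cfg$field_size
  ids <- sprintf("fld_%06d", seq_len(n))

  classes <- with_seed(child_seed(cfg$seed, "classes"), {
    sample(names(cfg$contamination), n, replace = TRUE, prob = cfg$contamination)
  })

  absorb <- matrix(0, n, cfg$n_wavelengths)
  truth <- matrix(0, n, length(traits), dimnames = list(NULL, traits))
  for (cl in names(cfg$contamination)) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    with_seed(child_seed(cfg$seed, paste0("class-", cl)), {
      m <- length(idx)
      z <- matrix(rnorm(m * cfg$n_latent), m, cfg$n_latent)
      if (cl == "extrapolated") {
        # out-of-calibration variability lives along the minor latent
        # directions: the upper half of the factors get an inflated SD and
        # the two least-calibrated ones a random-sign systematic shift.
        # Major composition axes stay population-typical, so extrapolated
        # records keep plausible trait values while their spectra leave
        # the calibration span.
        minor <- seq.int(floor(cfg$n_latent / 2) + 1L, cfg$n_latent)
        z[, minor] <- z[, minor] * cfg$extrapolation_shift
        last2 <- cfg$n_latent - c(1L, 0L)
        last2 <- last2[last2 >= 1L]
        sgn <- sample(c(-1, 1), m, replace = TRUE)
        z[, last2] <- z[, last2] + sgn * cfg$extrapolation_mean_shift
      }
      sp <- tcrossprod(z, model$loadings) +
        matrix(rnorm(m * cfg$n_wavelengths, 0, cfg$spectral_noise_sd),
               m, cfg$n_wavelengths)
      sp <- sweep(sp, 2, model$mean_curve, "+")
      if (cl == "degraded") {
        sev <- runif(m, cfg$degraded_severity_range[1], cfg$degraded_severity_range[2])
        base <- runif(m, cfg$degraded_baseline_range[1], cfg$degraded_baseline_range[2])
        sp <- sp + degraded_artifacts(cfg, m, sev) + base
      }
      absorb[idx, ] <- sp
      for (j in seq_along(traits)) {
        def <- cfg$trait_defs[j, ]
        truth[idx, j] <- trait_from_latent(z, model$beta, def$mean, def$sd,
                                            cfg$trait_noise_sd, m)
      }
    })
  }

  # mismatched records carry another record's spectrum; their own truth
  # (hence INT) is untouched
  mis <- which(classes == "mismatched")
  if (length(mis) && n > 1) {
    pool <- setdiff(seq_len(n), mis)
    donors <- with_seed(child_seed(cfg$seed, "mismatch"), {
      vapply(mis, function(i) {
        candidates <- if (length(pool)) pool else seq_len(n)[-i]
        candidates[sample.int(length(candidates), 1L)]
      }, integer(1))
    })
    absorb[mis, ] <- absorb[donors, , drop = FALSE]
  }

  spectra <- new_spectra(absorb, ids)

  records <- tibble::tibble(sample_id = ids, true_class = classes)
  meta <- with_seed(child_seed(cfg$seed, "metadata"), {
    n_cows <- max(1L, as.integer(round(n / 7)))
    tibble::tibble(
      cow_id = sprintf("cow_%05d", sample.int(n_cows, n, replace = TRUE)),
      days_in_milk = sample(5:365, n, replace = TRUE),
      lactation_number = pmin(1L + rpois(n, 1), 13L)
    )
  })
  records <- dplyr::bind_cols(records[, "sample_id"], meta,
                              records[, "true_class"])

  int_noise <- with_seed(child_seed(cfg$seed, "internal"), {
    matrix(rnorm(n * length(traits), 0, cfg$instrument_noise_sd),
           n, length(traits))
  })
  for (j in seq_along(traits)) {
    tr <- traits[j]
    ext <- predict(equations[[tr]], spectra)
    records[[paste0("true_", tr)]] <- truth[, j]
    records[[paste0("INT_", tr)]] <-
      cfg$slope * (truth[, j] + int_noise[, j]) + cfg$bias
    records[[paste0("EXT_", tr)]] <- ext$value
  }
  list(spectra = spectra, records = records)
}
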