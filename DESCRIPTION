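Package: mirqc
Title: Quality Assurance for Phenotypes Predicted from Milk Mid-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical quality-assurance tools for phenotypes predicted from
    milk mid-infrared (MIR) spectra, as used by dairy herd improvement
    organizations. Implements the Global-H (GH) applicability-domain score
    (squared Mahalanobis distance of a spectrum's principal-component scores to
    the calibration centroid, divided by the number of components), gap
    first-derivative preprocessing and piecewise spectral standardization,
    three record-cleaning rules (extreme-quantile deletion, GH thresholding,
    absolute fat-residual thresholding) with and/or combinations, and an
    evaluation framework based on the root mean square difference (RMSD)
    between internal (spectrometer) and external (equation) predictions:
    RMSD gain, data loss, gain:loss ratios, threshold sweeps with rank tests,
    and method-overlap summaries. A synthetic spectra generator with
    controlled outlier contamination (extrapolated, degraded and mismatched
    records) makes the whole pipeline testable end to end without
    proprietary milk-recording data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
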