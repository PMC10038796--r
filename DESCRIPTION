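Package: iscor
Title: Intersubject Correlation Analysis for Naturalistic Neuroimaging Time
    Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis stack for intersubject correlation (ISC) studies of
    multi-subject naturalistic-stimulus BOLD recordings: within- and
    across-condition ISC maps, nonparametric inference with chunk-shuffled
    surrogate time series, generalized-Pareto tail p-values and max-statistic
    familywise-error correction, model-mediated ISC (feature-model
    residualization and the drop statistic), temporal-receptive-window
    (chronotopic) mapping, and wavelet coherence of stimulus descriptor
    streams. Includes a synthetic-data generator with known ground truth for
    calibration and recovery testing, NIfTI/TSV input-output and an
    end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
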