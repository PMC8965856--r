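Package: qeegattn
Title: Quantitative EEG Spectral Dynamics as an Attention Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral analysis of multichannel scalp EEG for studying
    attention-related dynamics of the power spectrum: Welch power spectral
    density at 1-Hz resolution, band powers, 0-50 Hz normalized spectra,
    the theta/beta ratio, and the attention-to-resting alpha power ratio
    biomarker, together with the cohort statistics used to evaluate it
    (BMI z-scores, chi-square and Mann-Whitney group comparisons,
    per-frequency t-tests, Spearman correlations, and forward stepwise
    linear regression).  Includes a synthetic EEG and behavioral cohort
    generator with planted alpha suppression so the full pipeline is
    testable end to end, plus EDF input/output and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
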