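Package: ftirgrade
Title: Chemometric Grading of Meningioma ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested chemometric workflow for discriminating WHO grade I,
    grade II and recurrent grade I meningiomas from attenuated total
    reflection Fourier-transform infrared (ATR-FTIR) tissue spectra.
    Provides fingerprint-region truncation, Savitzky-Golay second-derivative
    filtering and vector normalisation, Hotelling T2/Q-residual outlier
    screening, Kennard-Stone sample partitioning with venetian-blinds
    cross-validation, PCA-LDA and PLS-DA discriminant models,
    accuracy/sensitivity/specificity and ROC/AUC evaluation,
    difference-between-mean spectral-biomarker extraction with per-wavenumber
    ANOVA, and a recurrence-candidate screen. Includes a synthetic cohort
    generator that emulates a realistic clinical acquisition design so that
    every stage is testable without access to patient spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    MASS,
    pROC
Config/testthat/edition: 3
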