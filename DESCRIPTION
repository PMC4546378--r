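Package: cqtcross
Title: Concentration-QTc Analysis of Crossover ECG Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cardiac-safety (C-QT) analysis of single-dose crossover
    trials with intensive ECG sampling. Reduces triplicate ECGs, fits and
    selects individual heart-rate corrections (QTcI) alongside Fridericia's
    QTcF, derives baseline-averaged and placebo-subtracted QTc changes, fits
    the per-time-point crossover mixed model and two series of linear mixed
    concentration-effect models with AIC-based selection, predicts the QTc
    effect at the geometric-mean Cmax with parametric and subject-resampling
    bootstrap confidence intervals, runs the meal-based ECG assay-sensitivity
    test, and performs non-compartmental pharmacokinetic analysis. A seeded
    synthetic-trial generator reproduces the statistical structure of a
    four-period single-ascending-dose crossover study so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
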