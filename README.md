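# cqtcross

Concentration-QTc (C-QT) analysis for single-dose crossover trials with
intensive ECG sampling.

Drug-induced prolongation of the heart-rate-corrected QT interval (QTc) is a
standard cardiac-safety concern in early clinical development. In a
four-period crossover single-ascending-dose study with triplicate 12-lead
ECGs, a drug-free baseline day in every period and PK sampling time-matched
to the ECGs, two complementary analyses answer the safety question:

* a **per-time-point analysis** of the change of QTc from the period's
  average baseline (ΔQTc), contrasting each dose against time-matched
  placebo (ΔΔQTc) with 90% confidence intervals, and
* **concentration-effect (C-QT) modelling**, regressing the QTc change on the
  time-matched plasma concentration in linear mixed models, and predicting
  the effect at the geometric-mean Cmax of each dose group.

Because such studies carry no pharmacological positive control, **assay
sensitivity** is demonstrated physiologically: a standardised meal reliably
shortens QTc by several ms, so the estimated postprandial change from
pre-dose (with 95% CIs, Bonferroni-style for the two tested times) must be
clearly negative for the assay to be declared sensitive.

`cqtcross` implements the full pipeline for biostatisticians and
pharmacometricians working on such trials, plus a seeded synthetic-trial
generator that reproduces the statistical structure of the design (4×4
crossover, 32 subjects, triplicate ECGs at 19 nominal times on a baseline
day and the dosing day, dose-proportional one-compartment PK, per-subject
QT-RR laws, a postprandial QTc shortening of about −8 ms, between-subject
QTc SD of 8 ms, and an optional linear drug effect on QTc), so every stage
can be exercised and validated without access to any proprietary raw data.

## The models

With `i` subjects, `p` periods, `t` nominal times, QTc is reduced per
(subject, period, day, time) to the median of the triplicate; the baseline
`QTc_baselineAV(i,p)` is the mean of the baseline-day per-time medians;
`ΔQTc = QTc − QTc_baselineAV`; `ΔΔQTc` subtracts the subject's time-matched
placebo ΔQTc. Heart-rate correction is Fridericia's `QTcF = QT/RR^(1/3)`
and an individual `QTcI` chosen per subject between `QT = a + b·RR`
(QTcI = QT − b(RR−1)) and `ln QT = a + b·ln RR` (QTcI = QT/RR^b) by the
smallest |corr(QTc, RR)|, then the smallest |slope of QTc on RR|, with
log-log preferred on full ties.

* **Time course:** `ΔQTc ~ sequence + period + sex + treatment×time +
  baselineAV`, random subject intercept (compound symmetry), 90% t-based CIs
  for each dose-vs-placebo contrast.
* **Series 1:** `ΔΔQTc ~ period + sequence + sex + conc` on active periods;
  variants add a random concentration slope or drop the fixed effects with a
  zero fixed intercept.
* **Series 2:** `ΔQTc ~ time + period + sequence + sex + conc` including
  placebo periods at concentration 0, so the spontaneous (meal-driven) time
  course is estimated jointly and the slope is corrected for it; the
  postprandial time effects double as the assay-sensitivity test.

Within each series the model with the better AIC is used for predictions at
the geometric-mean Cmax; when a predicted effect exceeds 5 ms in magnitude
the CI is recomputed by a subject-level bootstrap that also resamples the
Cmax distribution. Non-compartmental PK (Cmax, tmax, λz, t½, AUC0-t,
AUC0-24, AUC0-∞ by linear-up/log-down trapezoids) feeds the dose-group
summaries.

## Worked example

```r
library(cqtcross)

trial <- simulate_trial(n_subjects = 32, seed = 1,
                        qt_params = qt_model_params(drug_slope = -0.0008))
obs <- derive_qtc_observations(trial$ecg, trial$pk)

fit <- fit_series2(obs, variant = 2, qtc_variable = "QTcI")
fit
#> C-QT mixed model: series 2, variant 2, QTcI, analyte parent
#>   slope -0.00081827 ms/(ng/mL)  [95% CI -0.00092607, -0.00071047]
#>   AIC (ML) 13781.6, AIC (REML) 13797.1, n = 2432 obs / 32 subjects

nca <- nca_table(trial$pk)
predict_at_concentration(fit, geometric_mean_cmax(nca, 500))
#> Predicted QTcI effect at 4006.8 ng/mL: -3.28 ms [90% CI -3.64, -2.92] (parametric)

sens <- assay_sensitivity(obs)
sens$contrasts
#>   time_h estimate_ms    ci_low   ci_high significant
#> 1      6   -7.951998 -9.084992 -6.819005        TRUE
#> 2      8   -6.692939 -7.820387 -5.565491        TRUE
sens$criterion_met
#> [1] TRUE
```

The generator injected a slope of −0.0008 ms/(ng/mL) and a −8 ms meal
effect; the fitted slope (−0.00082, CI excluding 0), the roughly −3 ms
predicted shortening at the 500 mg geometric-mean Cmax (~4000 ng/mL), and
the clearly negative postprandial contrasts at 6 h and 8 h recover both.
`fit_timecourse()` + `largest_time_matched_difference()` give the
per-time-point view, and `run_pipeline(pipeline_config(...), out_dir)` runs
every stage and writes the full set of CSV outputs, a run log and a JSON
summary.

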