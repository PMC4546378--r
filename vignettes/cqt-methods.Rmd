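---
title: "Concentration-QTc analysis of a crossover trial: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration-QTc analysis of a crossover trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cqtcross)
```

`cqtcross` analyses single-dose, four-period crossover trials with intensive
ECG sampling: triplicate 12-lead ECGs at 19 nominal times on a drug-free
baseline day and on the dosing day of every period, with PK samples
time-matched to the ECGs. This vignette is the package's account of the
statistical methods, the synthetic-data generator that stands in for the
(unavailable) raw data, and the design decisions taken where more than one
reasonable implementation exists.

## 1. From raw ECGs to analysable observations

**Triplicate reduction.** Each (subject, period, day, time) cell is reduced
to the median of its replicates, each interval (QT, RR, corrected QTc)
independently. With an even number of surviving replicates the median is the
mean of the two central values. Medians, not means, because single automated
interval reads occasionally fail grossly.

**Heart-rate correction.** QTcF uses the canonical cube-root exponent
(`QT/RR^(1/3)`; RR in seconds). Reports sometimes print the rounded exponent
0.33 — the difference is below 0.5 ms at physiological RR and the exponent is
an argument throughout. The individual correction QTcI is fitted per subject
on all drug-free records (the baseline day of every period plus the
dosing-day records of the placebo period) at replicate level — replicates
rather than medians because the regression benefits from the extra points;
this is configurable upstream by reducing first. Two candidate models are
fitted by least squares, linear (`QT = a + b RR`, QTcI `= QT − b(RR−1)`) and
log-log (`ln QT = a + b ln RR`, QTcI `= QT/RR^b`), and the winner is chosen
by: (1) smaller |Pearson correlation of QTcI with RR|; (2) on a tie, smaller
|slope of QTcI regressed on RR|; (3) on a further tie, log-log. Ties are
compared to 1e-12 — exact ties are measure-zero with real data, so the rule
is kept literal. Subjects with fewer than 20 drug-free pairs or no RR
variation fall back to Fridericia with a warning. A subtlety uncovered by the
noise-free tests: when a correction is exact, the corrected QTc is constant
up to floating-point noise and its Pearson correlation with RR is the
correlation of that noise, i.e. arbitrary; correlations of numerically
constant QTc are therefore defined as 0.

**Baselines and changes.** The period baseline `QTc_baselineAV` is the
arithmetic mean of the baseline-day per-time medians; `ΔQTc` subtracts it;
`ΔΔQTc` subtracts the subject's time-matched placebo `ΔQTc` and is never
imputed when the placebo time point is missing. Concentration is joined on
nominal time; placebo and pre-dose concentrations are 0; ECG times with no
PK sample are left missing and counted.

## 2. The mixed models

All models are fitted by REML with `nlme::lme`; concentrations enter the
fixed part in µg/mL (a 1/1000 rescaling) so that random-slope variances are
well scaled for the optimiser, and slopes are reported back per ng/mL. This
rescaling is exactly undone in the reported estimates. Confidence intervals
are two-sided t intervals with `N − rank(X)` degrees of freedom; at roughly
2,300 observations per fit the difference from a Satterthwaite approximation
is negligible.

**Per-time-point model.** `ΔQTc ~ sequence + period + sex + treatment×time +
baselineAV(centred)` with a random subject intercept — the classical
compound-symmetry crossover analysis. Time is categorical with the pre-dose
level as reference; the baseline covariate is centred at its grand mean for
numerical stability. Dose-vs-placebo contrasts (treatment main effect plus
interaction) are reported with 90% CIs at every post-dose time, and the
largest time-matched difference per dose is taken over post-dose times up to
a configurable 24 h window, ties to the earliest time. Note the maximum of
noisy contrasts is positively biased under the null — the per-time view is
descriptive; inference rests on the concentration models.

**Series 1 (ΔΔQTc).** On active periods only: `ΔΔQTc ~ period + sequence +
sex + conc` (variant 1), plus a random concentration slope (variant 2), or
no fixed effects with the fixed intercept constrained to 0 and random
intercept and slope (variant 3).

**Series 2 (ΔQTc with time).** All periods, placebo at concentration 0:
`ΔQTc ~ time + period + sequence + sex + conc` with a random intercept
(variant 1) or additionally a random concentration slope (variant 2).
Because the spontaneous time course is estimated from every period, the
concentration slope is corrected for it, and the time effects themselves
carry the meal signal used for assay sensitivity.

**Covariance realisation.** "Compound symmetry" for change-from-baseline
data is realised as *nested* random intercepts, subject plus
subject-by-period. The reason is structural: every ΔQTc of one period shares
that period's baseline-average measurement error, so observations are
exchangeably correlated *within a period* over and above the subject level.
Simulation under the package's own generator shows that a subject-only
intercept understates the concentration-slope standard error (null z-scores
with SD ≈ 1.35; 90% CIs covering ~70–77%), while the nested structure
restores calibration (z-SD ≈ 0.95); the nested intercept is also what the
classical repeated-measures CS specification (subject-within-period blocks)
amounts to. Random slopes are at the subject level, matching the "plus
random slope" variants.

**AIC selection.** Within a series the best model is the one with the
smallest AIC. The default compares AICs from ML refits, because REML
likelihoods are not comparable across different fixed-effect structures
(variant 3 drops all fixed effects); `criterion = "reml"` reproduces the
alternative convention. Exact ties go to the model with fewer variance
parameters, then the lower variant number.

**Predictions.** For series 2 and the zero-intercept series-1 variant, the
predicted drug effect at concentration `c` is `slope × c`: between two
otherwise identical subjects, exposed and unexposed, every time and
covariate term cancels. For series-1 variants 1–2 the fixed intercept does
not cancel; the prediction adds the mean fixed-effect value at concentration
0 over the estimation data (the construction is not uniquely determined by
the model statement; this average-covariate choice is the package's).
Parametric CIs come from the variance of the fixed-effect linear
combination. When a point estimate exceeds 5 ms in magnitude the plan's
bootstrap kicks in: subjects are resampled with replacement, stratified by
sequence, and each replicate recomputes the geometric-mean Cmax *and*
refits the model before predicting, so the randomness of the mean Cmax is
propagated; the interval is the percentile interval (default B = 1000).

**Assay sensitivity.** From the best series-2 fit (QTcF by default), the
time effects at 6 h and 8 h (1 h and 3 h after the standardised lunch) are
contrasted against pre-dose with 95% CIs — fixed at 95% for the two
pre-specified times in the sense of a Bonferroni correction of a 90% family
level, not adapted to the number of requested times unless the level is
overridden. The criterion passes when every CI lies entirely below 0 and
every point estimate is at or below −5 ms ("well below −5 ms" is
operationalised as `estimate ≤ −5.0`, threshold configurable, since no
sharper definition exists).

## 3. Non-compartmental PK

Cmax/tmax by direct maximum (ties to the earliest time); AUC0-t to the last
quantifiable concentration by the linear-up/log-down trapezoid (the industry
default; all-linear available); AUC0-24 with log-interpolation at 24 h on a
declining segment; λz from the log-linear regression over the candidate
tail of 3–8 quantifiable points strictly after tmax with the best adjusted
R², requiring a negative slope; t½ = ln 2/λz; AUC0-∞ = AUC0-t + Clast/λz.
Profiles without an acceptable terminal fit keep their AUC0-t and are
flagged rather than failing. Dose-group summaries report arithmetic means
(SD), medians (SD) for tmax, the geometric-mean Cmax separately for the
effect predictions, and dose-normalised columns — by each group's own dose
by default, or by a fixed reference dose (`reference_dose`) to mirror
reports that normalise all groups to the lowest dose.

## 4. The synthetic-trial generator

The generator reproduces the design's statistical structure, not its
physiology in detail:

* 4×4 crossover, default 32 subjects allocated round-robin to the four
  sequences (placebo in period 1/2/3/4 respectively, ascending doses
  otherwise), 19 nominal times, triplicates, meals at 5 and 9 h post-dose on
  both study days. Sex alternates *within* each sequence group (≈16/16);
  alternating along the subject list would make sex a deterministic function
  of the sequence and alias the two factors.
* PK: one-compartment first-order absorption, `ka = 1.0 /h`, `t½ = 35 h`,
  V/F = 118 L tuned so 500 mg peaks near 3900 ng/mL; per-subject lognormal
  exposure multiplier (SD 0.2, a typical between-subject CV); optional
  metabolites as scaled parent curves (< 0.2× exposure); doses are exactly
  dose-proportional so NCA linearity is testable. With a single
  compartment, matching the observed Cmax at a 35 h terminal half-life
  overstates AUC relative to a distributive multi-compartment profile; the
  generator favours Cmax fidelity because Cmax drives the predictions.
* QTc process: per-subject baseline `N(405, 8²)` ms (8 ms between-subject
  SD), +12 ms for females, per-subject log-log QT-RR exponent `N(0.33,
  0.08²)`, RR `N(0.90, 0.08²)` s between subjects with 0.05 s within-subject
  SD (needed so individual corrections are estimable), triplicate
  measurement noise 6 ms on QT (typical for 10 s ECG reads; the source study
  reports neither replicate SD nor RR dispersion, so these are realistic
  defaults, documented, not claimed to match), optional cosine circadian
  term (off by default to keep the null clean), optional linear drug effect
  in ms per ng/mL.
* Food effect: an exponential shortening from each meal,
  `A·e^{−(t−t_meal)/τ}` for `t ≥ t_meal`, amplitude −8 ms. The decay τ
  defaults to 17 h, calibrated so the implied effects 1 h and 3 h after the
  lunch (−7.5 and −6.7 ms) match the magnitudes reported for this design
  (−8.1 and −7.2 ms): the ratio 7.2/8.1 over two hours pins τ ≈ 17 h. A
  faster decay (e.g. 4 h) would put the 8 h effect near −3.8 ms, shallower
  than anything observed postprandially in practice, and would make the
  −5 ms assay-sensitivity criterion unattainable by construction. Meals also
  transiently shorten RR (−0.04 s, same decay).
* Measured QT is `QTc_true · RR^{b_i}` plus replicate noise, so the
  generator's drug effect lives on the QTc scale and the correction step
  must undo the RR dependence to recover it.

What the generator does *not* emulate: beat-level morphology, circadian
structure beyond a single cosine, hysteresis between concentration and
effect, non-linear exposure-response, carryover across the 7-day washout,
outlier subjects, or missing-data mechanisms beyond an optional single
dropout. Passing tests therefore demonstrate that the pipeline recovers
known effects under the trial's correlation structure — not that any real
drug is safe.

A consequence worth knowing: because QTcI's per-subject coefficients are
estimated with error, an injected QTc-scale drug effect is transmitted into
measured QTcI with a gain slightly below 1 (about 5% attenuation under the
default noise model, e.g. when a linear correction is selected the drug
term is scaled by `RR^b ≈ 0.97`). QTcF has unit gain by construction. The
package's calibration checks therefore assert CI coverage on QTcF and bias
bounds on both scales; the same trade-off (fixed corrections beating
estimated ones in precision) is well known in practice.

## 5. Monte-Carlo validation and problem sizes

The test suite validates the pipeline at the design's own size — 200
simulated 32-subject trials per property: slope recovery of an injected
−0.0008 ms/(ng/mL) effect by the random-slope variants of both series (mean
bias well under 10%, 90% CI coverage within 86–94%), detection of the −8 ms
meal effect in ≥ 90% of trials with ≤ 5% false alarms when the amplitude is
0, and cancellation of the food effect in the double difference (|mean
ΔΔQTc| at postprandial times < 0.5 ms). Deterministic oracles cover the
NCA arithmetic (hand-computed trapezoids, analytic decay curves), the
correction selection rule (noise-free generated subjects), and the
prediction arithmetic against published slope values. The design-stage
power claim (28 subjects, 8 ms SD, 8 ms effect, two-sided 5%) is
reproduced by direct simulation of the paired t test (≥ 1000 trials;
empirical power ≈ 1.0, comfortably above the 90% design target).

## 6. Known limitations

* Series-1 double-difference CIs remain slightly anticonservative even with
  the nested covariance for the random-intercept-only variant, because the
  shared placebo-period noise projects onto the concentration profile; the
  random-slope variants absorb most of this and are the ones selected by
  AIC in practice.
* The λz tail search optimises adjusted R² over tail sizes 3–8; profiles
  with fewer than three declining quantifiable points after tmax get no
  terminal phase, by design.
* `run_pipeline()` is deterministic given the configuration seed; running
  stages manually with your own seeds is supported but then reproducibility
  is the caller's responsibility.
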