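# Shared fixtures, built once per test run.

# A small complete trial (8 subjects) with the default generator, plus its
# processed observation table; several test files reuse these.
small_trial <- simulate_trial(n_subjects = 8, seed = 101)
small_obs <- derive_qtc_observations(small_trial$ecg, small_trial$pk)

# Noise-free generator settings: every SD, the food effect and the drug off,
# a fixed QT-RR exponent, so QTc is exactly reconstructable.
noiseless_params <- function(exponent = 0.33, ...) {
  args <- list(qtc_between_subject_sd = 0, replicate_sd = 0,
               circadian_amplitude = 0, food_effect_amplitude = 0,
               drug_slope = 0, sex_effect = 0,
               rr_between_subject_sd = 0, rr_within_sd = 0.05,
               rr_food_drop_s = 0, qt_rr_exponent_mean = exponent,
               qt_rr_exponent_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(qt_model_params, args)
}

# Replicate-level drug-free ECG table for one synthetic subject whose true
# QT-RR law is known exactly.
synthetic_subject_records <- function(law = c("loglog", "linear"),
                                      n = 60, seed = 7,
                                      exponent = 0.25, slope = 60) {
  law <- match.arg(law)
  set.seed(seed)
  rr <- runif(n, 0.7, 1.1)
  qt <- switch(law,
               loglog = 420 * rr ^ exponent,
               linear = 350 + slope * rr)
  data.frame(subject_id = "X01", period = 1L, day = -1L,
             treatment = "placebo", nominal_time_h = seq_len(n),
             replicate = 1L, qt_ms = qt, rr_s = rr,
             stringsAsFactors = FALSE)
}
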