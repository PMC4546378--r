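test_that("simulated concentrations match the closed form when variability is off", {
  design <- build_design(8)
  pars <- default_pk_params()
  pk <- simulate_pk(design, pars, seed = 1, iiv_sdlog = 0)
  for (trt in names(pars)) {
    rows <- pk[pk$treatment == trt, ]
    expect_equal(rows$conc_ng_ml,
                 conc_profile(rows$nominal_time_h, pars[[trt]]),
                 tolerance = 1e-9)
  }
  # no drug at the dosing instant, placebo zero throughout
  expect_true(all(pk$conc_ng_ml[pk$nominal_time_h == 0] == 0))
  expect_true(all(pk$conc_ng_ml[pk$treatment == "placebo"] == 0))
})

test_that("concentration scales linearly with dose when variability is off", {
  design <- build_design(4)
  p1 <- list("500 mg" = pk_params(500))
  p2 <- list("500 mg" = pk_params(1000))
  c1 <- simulate_pk(design, p1, seed = 2, iiv_sdlog = 0)
  c2 <- simulate_pk(design, p2, seed = 2, iiv_sdlog = 0)
  on <- c1$treatment == "500 mg"
  expect_equal(c2$conc_ng_ml[on], 2 * c1$conc_ng_ml[on], tolerance = 1e-12)
})

test_that("degenerate absorption (ka = ke) is rejected", {
  expect_error(pk_params(500, ka = log(2) / 35, t_half = 35), "ke")
})

test_that("noiseless generator yields a constant reconstructable QTc", {
  qp <- noiseless_params(exponent = 0.33)
  tr <- simulate_trial(8, seed = 5, qt_params = qp, iiv_sdlog = 0)
  qtc <- tr$ecg$qt_ms / tr$ecg$rr_s ^ 0.33
  expect_lt(diff(range(qtc)), 1e-9)
  expect_equal(unique(round(qtc, 9)), 405)
})

test_that("the injected food term equals its analytic value before noise", {
  qp <- noiseless_params(exponent = 0.33,
                         food_effect_amplitude = -8, food_effect_decay_h = 4)
  tr <- simulate_trial(8, seed = 5, qt_params = qp, iiv_sdlog = 0)
  qtc <- tr$ecg$qt_ms / tr$ecg$rr_s ^ 0.33
  at <- function(t) mean(qtc[tr$ecg$nominal_time_h == t])
  # 6 h = 1 h after the 5 h lunch: -8 * exp(-1/4)
  expect_equal(at(6) - at(0), -8 * exp(-1 / 4), tolerance = 1e-9)
  # 12 h: lunch (7 h ago) + dinner (3 h ago) superpose
  expect_equal(at(12) - at(0), -8 * (exp(-7 / 4) + exp(-3 / 4)),
               tolerance = 1e-9)
  # pre-meal times carry no food effect
  expect_equal(at(4) - at(0), 0, tolerance = 1e-9)
})

test_that("identical seeds reproduce the trial bit for bit", {
  t1 <- simulate_trial(8, seed = 99)
  t2 <- simulate_trial(8, seed = 99)
  expect_identical(t1$ecg, t2$ecg)
  expect_identical(t1$pk, t2$pk)
  t3 <- simulate_trial(8, seed = 100)
  expect_false(identical(t1$ecg$qt_ms, t3$ecg$qt_ms))
})

test_that("simulated Cmax geometric mean scales linearly with dose", {
  design <- build_design(8)
  pk <- simulate_pk(design, default_pk_params(), seed = 3, iiv_sdlog = 0)
  nca <- nca_table(pk)
  gm <- sapply(c(500, 600, 800), function(d) geometric_mean_cmax(nca, d))
  expect_equal(gm[2] / gm[1], 600 / 500, tolerance = 1e-6)
  expect_equal(gm[3] / gm[1], 800 / 500, tolerance = 1e-6)
})

test_that("metabolite curves are scaled copies of the parent", {
  design <- build_design(4)
  pk <- simulate_pk(design, default_pk_params(), seed = 4, iiv_sdlog = 0,
                    metabolites = TRUE)
  par_rows <- pk[pk$analyte == "parent", ]
  m1 <- pk[pk$analyte == "M1", ]
  expect_equal(m1$conc_ng_ml, 0.15 * par_rows$conc_ng_ml, tolerance = 1e-12)
  expect_lt(max(m1$conc_ng_ml) / max(par_rows$conc_ng_ml), 0.2)
})

test_that("optional dropout removes one subject's later periods", {
  tr <- simulate_trial(8, seed = 6, dropout = TRUE)
  full <- 4 * 2 * 19 * 3  # periods x days x times x replicates
  counts <- table(factor(tr$ecg$subject_id,
                         levels = tr$design$subjects$subject_id))
  expect_equal(sum(counts < full), 1L)
  expect_lt(nrow(tr$ecg), 8 * full)
})

test_that("simulate_ecg demands full PK coverage of the design", {
  design <- build_design(4)
  pk <- simulate_pk(design, default_pk_params(), seed = 1)
  expect_error(simulate_ecg(design, pk[pk$nominal_time_h != 4, ],
                            qt_model_params(), seed = 1),
               "does not cover")
})
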