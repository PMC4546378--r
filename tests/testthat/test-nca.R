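test_that("linear-up/log-down trapezoid matches hand computation", {
  r <- run_nca(c(0, 1, 2), c(0, 10, 5))
  # up 0->10: 1 * (0+10)/2 = 5 ; down 10->5: (10-5)/log(10/5)
  expect_equal(r$auc_0_t, 5 + 5 / log(2), tolerance = 1e-6)
  expect_equal(r$cmax, 10)
  expect_equal(r$tmax, 1)
  # all-linear rule on the same profile
  expect_equal(run_nca(c(0, 1, 2), c(0, 10, 5), method = "linear")$auc_0_t,
               5 + 7.5)
})

test_that("log-down reduces to the linear rule on flat segments", {
  expect_equal(run_nca(c(0, 1, 2, 3), c(0, 10, 10, 5))$auc_0_t,
               5 + 10 + 5 / log(2), tolerance = 1e-9)
})

test_that("a two-point terminal window gives the exact half-life", {
  r <- run_nca(c(0, 1, 24, 48), c(0, 20, 10, 5), lambda_tail_range = 2)
  expect_equal(r$t_half, 24, tolerance = 1e-9)
  expect_equal(r$n_lambda_points, 2L)
})

test_that("dense monoexponential decay recovers half-life and AUC", {
  t <- c(0, seq(0.5, 96, by = 0.5))
  conc <- 100 * exp(-log(2) / 24 * t)
  conc[1] <- 0  # pre-dose
  r <- run_nca(t, conc)
  expect_equal(r$t_half, 24, tolerance = 0.1)
  # true AUC0-inf of the exponential tail from 0.5 h plus the initial segment
  true_auc <- 100 / (log(2) / 24)
  expect_lt(abs(r$auc_0_inf - true_auc) / true_auc, 0.02)
})

test_that("dense one-compartment profile matches Dose/(CL/F) and the true peak", {
  p <- pk_params(500)
  t <- c(0, seq(0.1, 240, by = 0.1))
  r <- run_nca(t, conc_profile(t, p), dose_mg = 500)
  cl <- p$v_over_f * p$ke                      # L/h
  true_auc <- 500 * 1e6 / (cl * 1e3)           # ng·h/mL
  expect_lt(abs(r$auc_0_inf - true_auc) / true_auc, 0.02)
  true_tmax <- log(p$ka / p$ke) / (p$ka - p$ke)
  expect_lt(abs(r$tmax - true_tmax), 0.1)
  expect_equal(r$t_half, 35, tolerance = 0.1)
})

test_that("AUC and Cmax scale with concentration; tmax and t1/2 do not", {
  t <- c(0, 1, 2, 4, 8, 24, 48)
  conc <- c(0, 8, 10, 7, 4, 1, 0.3)
  a <- run_nca(t, conc)
  b <- run_nca(t, 2 * conc)
  expect_equal(b$cmax, 2 * a$cmax)
  expect_equal(b$auc_0_t, 2 * a$auc_0_t, tolerance = 1e-12)
  expect_equal(b$auc_0_inf, 2 * a$auc_0_inf, tolerance = 1e-9)
  expect_equal(b$tmax, a$tmax)
  expect_equal(b$t_half, a$t_half, tolerance = 1e-9)
})

test_that("Cmax ties resolve to the earliest time", {
  r <- run_nca(c(0, 1, 2, 3, 6), c(0, 10, 10, 4, 1))
  expect_equal(r$tmax, 1)
})

test_that("AUC orderings hold on simulated profiles", {
  nca <- nca_table(small_trial$pk)
  expect_true(all(nca$auc_0_24 <= nca$auc_0_t + 1e-9))
  expect_true(all(nca$auc_0_t <= nca$auc_0_inf + 1e-9))
  expect_true(all(nca$tmax > 0))
})

test_that("profiles too sparse for a terminal fit are flagged, not fatal", {
  r <- run_nca(c(0, 1, 2, 3), c(0, 5, 10, 9))  # only 1 declining point after tmax
  expect_true(is.na(r$t_half))
  expect_identical(r$flags, "no_terminal_fit")
  expect_false(is.na(r$auc_0_t))
})

test_that("dose-group summary handles singletons and normalisation", {
  one <- data.frame(subject_id = "S1", period = 1, dose_mg = 500,
                    analyte = "parent", cmax = 4000, tmax = 2, t_half = 30,
                    auc_0_t = 70000, auc_0_24 = 36000, auc_0_inf = 80000,
                    lambda_z = 0.02, n_lambda_points = 3, r2_adj = 1)
  s <- summarize_dose_group(one)
  expect_equal(s$n, 1L)
  expect_equal(s$cmax_mean, 4000)
  expect_equal(s$cmax_sd, 0)
  # dose normalisation by the row's own dose and by a fixed reference
  expect_equal(round(dose_normalise(3938.5, 500), 1), 7.9)
  expect_equal(round(dose_normalise(36898.5, 500), 1), 73.8)
  expect_equal(dose_normalise(5580.1, 800, reference_dose = 500),
               5580.1 / 500)
})
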