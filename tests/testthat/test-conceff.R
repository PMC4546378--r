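test_that("negating the response flips the fitted slope exactly", {
  f <- fit_series1(small_obs, 1, "QTcI", ml_aic = FALSE)
  o2 <- small_obs
  o2$ddqtci_ms <- -o2$ddqtci_ms
  f2 <- fit_series1(o2, 1, "QTcI", ml_aic = FALSE)
  expect_equal(f2$slope, -f$slope, tolerance = 1e-8)
})

test_that("rescaling concentrations rescales the slope and not the predictions", {
  f <- fit_series2(small_obs, 1, "QTcI", ml_aic = FALSE)
  o2 <- small_obs
  o2$conc_ng_ml <- o2$conc_ng_ml * 3
  f2 <- fit_series2(o2, 1, "QTcI", ml_aic = FALSE)
  expect_equal(f2$slope, f$slope / 3, tolerance = 1e-6)
  p1 <- predict_at_concentration(f, 4000)
  p2 <- predict_at_concentration(f2, 12000)
  expect_equal(p2$point, p1$point, tolerance = 1e-6)
  expect_equal(p2$ci_low, p1$ci_low, tolerance = 1e-6)
})

test_that("series preconditions reject unusable inputs", {
  no_pbo <- small_obs[small_obs$dose_mg > 0, ]
  expect_error(fit_series2(no_pbo, 1, "QTcI"), "placebo")
  pbo_only <- small_obs[small_obs$dose_mg == 0, ]
  expect_error(fit_series1(pbo_only, 1, "QTcI"), "active")
  zero_conc <- small_obs
  zero_conc$conc_ng_ml <- 0
  expect_error(fit_series1(zero_conc, 1, "QTcI"), "zero")
  expect_error(fit_series2(zero_conc, 1, "QTcI"), "zero")
})

test_that("all series-1 and series-2 variants fit and carry both AICs", {
  for (v in 1:3) {
    f <- fit_series1(small_obs, v, "QTcI")
    expect_s3_class(f, "cqt_fit")
    expect_true(is.finite(f$aic_ml) && is.finite(f$aic_reml))
    expect_true(f$ci_low <= f$slope && f$slope <= f$ci_high)
  }
  f3 <- fit_series1(small_obs, 3, "QTcI")
  expect_equal(f3$intercept, 0)
  for (v in 1:2) {
    f <- fit_series2(small_obs, v, "QTcF")
    expect_true(is.finite(f$aic_ml))
    expect_equal(f$time_levels[1], "0")
  }
})

test_that("AIC selection picks the smallest criterion with documented ties", {
  mk <- function(variant, aic) conc_effect_fit(-5e-4, series = 1,
                                               variant = variant, aic_ml = aic)
  best <- select_by_aic(list(mk(1, 8985.8), mk(2, 8882.0), mk(3, 8908.3)))
  expect_equal(best$variant, 2)
  expect_equal(best$aic_ml, 8882.0)
  tab <- attr(best, "aic_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$best_fit, c(FALSE, TRUE, FALSE))
  # singleton
  expect_equal(select_by_aic(list(mk(3, 100)))$variant, 3)
  # exact tie -> fewer variance parameters (variant 1 here)
  expect_equal(select_by_aic(list(mk(1, 50), mk(2, 50)))$variant, 1)
  expect_error(select_by_aic(list()), "empty")
})

test_that("geometric mean Cmax follows its definition", {
  expect_equal(geometric_mean(c(4, 4, 4)), 4)
  expect_equal(geometric_mean(c(1, 100)), 10)
  x <- exp(rnorm(50, 1, 0.4))
  expect_lt(geometric_mean(x), mean(x))
  nca <- data.frame(subject_id = c("a", "b"), dose_mg = 500,
                    analyte = "parent", cmax = c(1, 100))
  expect_equal(as.numeric(geometric_mean_cmax(nca, 500)), 10)
  nca$cmax[1] <- -1
  expect_error(geometric_mean_cmax(nca, 500), "positive")
})

test_that("published slopes reproduce the printed Cmax-level predictions", {
  qtci <- conc_effect_fit(slope = -0.00079, series = 2)
  expect_equal(round(predict_at_concentration(qtci, 5464.0)$point, 1), -4.3)
  expect_equal(round(predict_at_concentration(qtci, 4302.4)$point, 1), -3.4)
  qtcf <- conc_effect_fit(slope = -0.00007, series = 2)
  expect_equal(round(predict_at_concentration(qtcf, 5464.0)$point, 1), -0.4)
  # zero concentration predicts exactly zero for slope-only models
  expect_equal(predict_at_concentration(qtci, 0)$point, 0)
  expect_error(predict_at_concentration(qtci, -1), "nonnegative")
})

test_that("fitted-model predictions carry t-based intervals around the point", {
  f <- fit_series2(small_obs, 1, "QTcI", ml_aic = FALSE)
  p <- predict_at_concentration(f, 4000)
  expect_true(p$ci_low <= p$point && p$point <= p$ci_high)
  expect_equal(p$point, f$slope * 4000)
  # series-1 variant 1 prediction includes the intercept contribution
  f1 <- fit_series1(small_obs, 1, "QTcI", ml_aic = FALSE)
  p1 <- predict_at_concentration(f1, 4000)
  expect_equal(p1$point, f1$intercept + f1$slope * 4000, tolerance = 1e-9)
})

test_that("bootstrap intervals are seeded and collapse for cloned subjects", {
  nca <- nca_table(small_trial$pk)
  b1 <- bootstrap_prediction_ci(small_obs, nca, 500, series = 1, variant = 1,
                                qtc_variable = "QTcI", B = 200, seed = 21)
  b2 <- bootstrap_prediction_ci(small_obs, nca, 500, series = 1, variant = 1,
                                qtc_variable = "QTcI", B = 200, seed = 21)
  expect_equal(b1$ci_low, b2$ci_low)
  expect_equal(b1$ci_high, b2$ci_high)
  expect_equal(b1$method, "bootstrap")

  # clone one subject across all ids: resampling has nothing to vary
  tpl_o <- small_obs[small_obs$subject_id == "S01", ]
  tpl_n <- nca[nca$subject_id == "S01", ]
  ids <- sprintf("C%02d", 1:8)
  clone_o <- do.call(rbind, lapply(seq_along(ids), function(i) {
    x <- tpl_o
    x$subject_id <- ids[i]
    x$sequence_id <- ((i - 1) %% 4) + 1
    x$sex <- c("M", "F")[((i - 1) %/% 4) + 1]
    x
  }))
  attr(clone_o, "analyte") <- "parent"
  clone_n <- do.call(rbind, lapply(seq_along(ids), function(i) {
    x <- tpl_n; x$subject_id <- ids[i]; x
  }))
  bc <- bootstrap_prediction_ci(clone_o, clone_n, 500, series = 1, variant = 1,
                                qtc_variable = "QTcI", B = 200, seed = 3)
  expect_equal(bc$ci_low, bc$point, tolerance = 1e-6)
  expect_equal(bc$ci_high, bc$point, tolerance = 1e-6)
})
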