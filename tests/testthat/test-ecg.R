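test_that("Fridericia correction behaves as QT / cube-root RR", {
  expect_equal(fridericia(400, 1.0), 400)
  expect_equal(fridericia(400, 0.64), 400 / 0.64 ^ (1 / 3), tolerance = 1e-12)
  expect_equal(round(fridericia(400, 0.64), 2), 464.16)
  # tachycardia (RR < 1 s) corrects upwards
  expect_gt(fridericia(400, 0.8), 400)
  expect_lt(fridericia(400, 1.2), 400)
  expect_error(fridericia(400, 0), "positive")
})

test_that("triplicate reduction takes per-cell medians, even counts averaged", {
  rec <- data.frame(subject_id = "S1", period = 1L, day = 1L,
                    treatment = "placebo", nominal_time_h = 1,
                    replicate = 1:3, qt_ms = c(398, 402, 410),
                    rr_s = c(1, 1, 1))
  expect_equal(reduce_triplicates(rec)$qt_ms, 402)
  rec$qt_ms <- c(400, 400, 400)
  expect_equal(reduce_triplicates(rec)$qt_ms, 400)
  two <- rec[1:2, ]; two$qt_ms <- c(398, 402)
  red2 <- reduce_triplicates(two)
  expect_equal(red2$qt_ms, 400)
  expect_equal(red2$n_replicates, 2L)
})

test_that("triplicate reduction is invariant to replicate order", {
  rec <- small_trial$ecg[small_trial$ecg$subject_id == "S01", ]
  shuffled <- rec[sample.int(nrow(rec)), ]
  a <- reduce_triplicates(rec)
  b <- reduce_triplicates(shuffled)
  expect_equal(a, b)
})

test_that("noise-free log-log subjects are fitted and selected exactly", {
  rec <- synthetic_subject_records("loglog", exponent = 0.25)
  fits <- fit_individual_corrections(rec, n_min = 20)
  ll <- fits[fits$method == "loglog", ]
  expect_equal(ll$slope_or_exponent, 0.25, tolerance = 1e-9)
  expect_equal(ll$residual_corr, 0, tolerance = 1e-9)
  sel <- select_corrections(fits)
  expect_equal(sel$method, "loglog")
})

test_that("noise-free linear subjects are fitted and selected exactly", {
  rec <- synthetic_subject_records("linear", slope = 60)
  fits <- fit_individual_corrections(rec, n_min = 20)
  lin <- fits[fits$method == "linear", ]
  expect_equal(lin$slope_or_exponent, 60, tolerance = 1e-9)
  expect_equal(lin$residual_corr, 0, tolerance = 1e-9)
  expect_equal(select_corrections(fits)$method, "linear")
})

test_that("degenerate or sparse drug-free data falls back to Fridericia", {
  rec <- synthetic_subject_records("linear")
  rec$rr_s <- 0.9  # no RR variation
  expect_warning(fits <- fit_individual_corrections(rec), "Fridericia")
  expect_equal(fits$method, "fridericia")
  expect_warning(fit_individual_corrections(synthetic_subject_records()[1:5, ]),
                 "Fridericia")
})

test_that("the three-step selection rule is applied literally", {
  mk <- function(method, r, s) data.frame(subject_id = "S1", method = method,
                                          slope_or_exponent = 1, intercept = 0,
                                          residual_corr = r, qtc_rr_slope = s,
                                          n_points = 30)
  # step 1: smaller |correlation| wins
  expect_equal(select_correction(mk("linear", 0.10, 5), mk("loglog", 0.02, 9))$method,
               "loglog")
  expect_equal(select_correction(mk("linear", -0.01, 5), mk("loglog", 0.02, 9))$method,
               "linear")
  # step 2: equal |r|, smaller |QTc-on-RR slope| wins
  expect_equal(select_correction(mk("linear", 0.05, 2), mk("loglog", -0.05, 4))$method,
               "linear")
  # step 3: full tie goes to log-log
  expect_equal(select_correction(mk("linear", 0.05, 3), mk("loglog", 0.05, -3))$method,
               "loglog")
})

test_that("selected QTcI decorrelates from RR at least as well as QTcF", {
  d <- small_trial$ecg
  d$qtcf_ms <- fridericia(d$qt_ms, d$rr_s)
  corr <- select_corrections(fit_individual_corrections(d))
  offdrug <- d[d$day == -1 | (d$day == 1 & d$treatment == "placebo"), ]
  for (k in seq_len(nrow(corr))) {
    di <- offdrug[offdrug$subject_id == corr$subject_id[k], ]
    qtci <- cqtcross:::apply_correction(di$qt_ms, di$rr_s, corr[k, ])
    expect_lte(abs(cor(qtci, di$rr_s)),
               abs(cor(di$qtcf_ms, di$rr_s)) + 1e-9)
  }
})

test_that("average baseline is the mean of baseline-day medians", {
  red <- data.frame(subject_id = "S1", period = 1L, day = -1L,
                    treatment = "placebo", nominal_time_h = c(0, 1),
                    qtcf_ms = c(400, 404), qtci_ms = c(410, 410))
  b <- compute_baseline_av(red)
  expect_equal(b$baseline_av_qtcf_ms, 402)
  expect_equal(b$baseline_av_qtci_ms, 410)
})

test_that("noiseless baselines recover the generator's true subject QTc", {
  qp <- noiseless_params(exponent = 1 / 3)  # matches the QTcF exponent
  tr <- simulate_trial(8, seed = 31, qt_params = qp, iiv_sdlog = 0)
  obs <- derive_qtc_observations(tr$ecg, tr$pk)
  expect_equal(unique(round(obs$baseline_av_qtcf_ms, 6)), 405)
  expect_true(all(abs(obs$dqtcf_ms) < 1e-6))
  expect_true(all(abs(obs$ddqtcf_ms[!is.na(obs$ddqtcf_ms)]) < 1e-6))
})

test_that("delta arithmetic: ddQTc is the time-matched double difference", {
  o <- small_obs
  expect_equal(o$dqtci_ms, o$qtci_ms - o$baseline_av_qtci_ms)
  # spot-check one active cell against its placebo partner
  a <- o[o$dose_mg > 0 & !is.na(o$ddqtci_ms), ][1, ]
  p <- o[o$subject_id == a$subject_id & o$treatment == "placebo" &
           o$nominal_time_h == a$nominal_time_h, ]
  expect_equal(a$ddqtci_ms, a$dqtci_ms - p$dqtci_ms)
  # placebo rows carry no double difference
  expect_true(all(is.na(o$ddqtci_ms[o$treatment == "placebo"])))
})

test_that("ddQTc is invariant to per-subject-period constant shifts", {
  ecg <- small_trial$ecg
  shift <- ave(seq_len(nrow(ecg)), ecg$subject_id, ecg$period,
               FUN = function(i) 7 * (i[1] %% 5))
  ecg2 <- ecg
  # shift QT so that QTcF moves by a per-period constant at RR = 1
  ecg2$qt_ms <- ecg2$qt_ms + shift * ecg2$rr_s ^ (1 / 3)
  o1 <- derive_qtc_observations(small_trial$ecg, small_trial$pk)
  o2 <- derive_qtc_observations(ecg2, small_trial$pk)
  expect_equal(o2$ddqtcf_ms, o1$ddqtcf_ms, tolerance = 1e-9)
})

test_that("RR in milliseconds is detected and converted", {
  rec <- small_trial$ecg[1:30, ]
  rec_ms <- rec; rec_ms$rr_s <- rec_ms$rr_s * 1000
  expect_message(red <- reduce_triplicates(cqtcross:::canonicalise_ecg(rec_ms)),
                 "milliseconds")
  expect_equal(red$rr_s, reduce_triplicates(rec)$rr_s, tolerance = 1e-12)
})
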