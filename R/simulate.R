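#' One-compartment PK parameters for one dose level
#'
#' @param dose_mg dose in mg.
#' @param ka first-order absorption rate, 1/h.
#' @param t_half terminal half-life, h.
#' @param v_over_f apparent volume of distribution V/F, litres.
#' @return list of class `cqt_pk_params`.
#' @details The elimination rate is `ke = log(2)/t_half` and must be smaller
#'   than `ka` (no flip-flop kinetics by default). The default volume is tuned
#'   so a 500 mg dose peaks near 3900 ng/mL, with fast absorption and a slow
#'   (35 h) terminal phase.
#' @export
pk_params <- function(dose_mg, ka = 1.0, t_half = 35, v_over_f = 118) {
  stopifnot(dose_mg >= 0, ka > 0, t_half > 0, v_over_f > 0)
  ke <- log(2) / t_half
  if (ke >= ka) stop("requires ke = log(2)/t_half < ka")
  structure(list(dose_mg = dose_mg, ka = ka, t_half = t_half,
                 v_over_f = v_over_f, ke = ke),
            class = "cqt_pk_params")
}

#' Default PK parameter sets for the three active dose levels
#'
#' @param doses_mg dose levels in mg.
#' @param ... passed to [pk_params()].
#' @return named list of `cqt_pk_params`, keyed "500 mg" etc.
#' @export
default_pk_params <- function(doses_mg = c(500, 600, 800), ...) {
  out <- lapply(doses_mg, pk_params, ...)
  names(out) <- paste(doses_mg, "mg")
  out
}

#' Closed-form one-compartment concentration profile
#'
#' `C(t) = dose * ka / (V/F * (ka - ke)) * (exp(-ke t) - exp(-ka t))`, with the
#' dose converted mg -> ng and the volume L -> mL so concentrations come out in
#' ng/mL.
#'
#' @param t hours post-dose (vector).
#' @param params a `cqt_pk_params`.
#' @return concentrations in ng/mL.
#' @export
conc_profile <- function(t, params) {
  stopifnot(inherits(params, "cqt_pk_params"))
  if (abs(params$ka - params$ke) < 1e-12) {
    stop("degenerate model: ka equals ke")
  }
  scale <- params$dose_mg * 1e6 / (params$v_over_f * 1e3)
  scale * params$ka / (params$ka - params$ke) *
    (exp(-params$ke * t) - exp(-params$ka * t))
}

#' Simulate plasma concentrations for a crossover trial
#'
#' Evaluates the one-compartment profile at every design time point for each
#' subject's active periods and multiplies by a per-subject lognormal
#' bioavailability/clearance factor. Placebo periods get concentration 0 at
#' all times. Metabolites, when requested, are simulated as scaled copies of
#' the parent curve (each well below 20% of parent exposure), mirroring
#' metabolites with a PK profile similar to the parent but several-fold lower
#' exposure.
#'
#' @param design a `cqt_design`.
#' @param params named list of `cqt_pk_params`, one per active treatment label
#'   (e.g. "500 mg").
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param iiv_sdlog between-subject lognormal SD of the exposure multiplier
#'   (0 switches variability off).
#' @param metabolites logical; also emit metabolite analytes M1-M5?
#' @param metabolite_fractions named scaling factors for the metabolite curves.
#' @return data.frame: subject_id, period, treatment, dose_mg, analyte,
#'   nominal_time_h, conc_ng_ml (dosing-day samples).
#' @export
simulate_pk <- function(design, params = default_pk_params(), seed = NULL,
                        iiv_sdlog = 0.2, metabolites = FALSE,
                        metabolite_fractions = c(M1 = 0.15, M2 = 0.12, M3 = 0.10,
                                                 M4 = 0.08, M5 = 0.06)) {
  stopifnot(inherits(design, "cqt_design"), iiv_sdlog >= 0)
  if (!is.null(seed)) set.seed(seed)
  tt <- treatment_table(design)
  subs <- design$subjects
  mult <- setNames(exp(rnorm(nrow(subs), 0, iiv_sdlog)), subs$subject_id)

  times <- design$nominal_times_h
  grid <- tt[rep(seq_len(nrow(tt)), each = length(times)), ]
  grid$nominal_time_h <- rep(times, nrow(tt))
  grid$conc_ng_ml <- 0
  for (trt in names(params)) {
    idx <- grid$treatment == trt
    if (!any(idx)) next
    grid$conc_ng_ml[idx] <- conc_profile(grid$nominal_time_h[idx], params[[trt]]) *
      mult[grid$subject_id[idx]]
  }
  grid$analyte <- "parent"
  out <- grid[, c("subject_id", "period", "treatment", "dose_mg", "analyte",
                  "nominal_time_h", "conc_ng_ml")]
  if (metabolites) {
    mets <- lapply(names(metabolite_fractions), function(m) {
      g <- out
      g$analyte <- m
      g$conc_ng_ml <- g$conc_ng_ml * metabolite_fractions[[m]]
      g
    })
    out <- rbind(out, do.call(rbind, mets))
  }
  rownames(out) <- NULL
  out
}

#' QT/QTc model parameters for the ECG simulator
#'
#' Governs the true per-subject QTc process and its mapping to measured
#' (QT, RR) pairs. Units are ms for QT-scale quantities and seconds for RR.
#'
#' @param qtc_pop_mean population mean baseline QTc, ms.
#' @param qtc_between_subject_sd between-subject SD of baseline QTc, ms.
#' @param replicate_sd within-triplicate measurement SD added to QT, ms.
#' @param circadian_amplitude amplitude of a 24 h cosine on QTc, ms (0 = off).
#' @param food_effect_amplitude immediate postprandial QTc change, ms
#'   (negative = shortening).
#' @param food_effect_decay_h exponential decay constant of the food effect, h.
#' @param drug_slope linear drug effect on QTc, ms per ng/mL.
#' @param sex_effect additive QTc offset for female subjects, ms.
#' @param rr_mean_s population mean resting RR, s.
#' @param rr_between_subject_sd between-subject SD of mean RR, s.
#' @param rr_within_sd within-subject (time point to time point) RR SD, s.
#' @param rr_food_drop_s transient postprandial RR shortening, s (decays with
#'   `food_effect_decay_h`).
#' @param qt_rr_exponent_mean,qt_rr_exponent_sd mean and between-subject SD of
#'   the true per-subject log-log QT-RR exponent.
#' @return list of class `cqt_qt_params`.
#' @export
qt_model_params <- function(qtc_pop_mean = 405,
                            qtc_between_subject_sd = 8,
                            replicate_sd = 6,
                            circadian_amplitude = 0,
                            food_effect_amplitude = -8,
                            food_effect_decay_h = 17,
                            drug_slope = 0,
                            sex_effect = 12,
                            rr_mean_s = 0.9,
                            rr_between_subject_sd = 0.08,
                            rr_within_sd = 0.05,
                            rr_food_drop_s = 0.04,
                            qt_rr_exponent_mean = 0.33,
                            qt_rr_exponent_sd = 0.08) {
  p <- list(qtc_pop_mean = qtc_pop_mean,
            qtc_between_subject_sd = qtc_between_subject_sd,
            replicate_sd = replicate_sd,
            circadian_amplitude = circadian_amplitude,
            food_effect_amplitude = food_effect_amplitude,
            food_effect_decay_h = food_effect_decay_h,
            drug_slope = drug_slope,
            sex_effect = sex_effect,
            rr_mean_s = rr_mean_s,
            rr_between_subject_sd = rr_between_subject_sd,
            rr_within_sd = rr_within_sd,
            rr_food_drop_s = rr_food_drop_s,
            qt_rr_exponent_mean = qt_rr_exponent_mean,
            qt_rr_exponent_sd = qt_rr_exponent_sd)
  sds <- c("qtc_between_subject_sd", "replicate_sd", "rr_between_subject_sd",
           "rr_within_sd", "qt_rr_exponent_sd")
  if (any(unlist(p[sds]) < 0)) stop("standard deviations must be nonnegative")
  if (p$food_effect_decay_h <= 0) stop("food_effect_decay_h must be > 0")
  if (p$rr_mean_s <= 0) stop("rr_mean_s must be > 0")
  structure(p, class = "cqt_qt_params")
}

#' Postprandial QTc (or RR) food term
#'
#' Exponentially decaying meal effect, summed over meals: for each meal time
#' `t_m`, contributes `amplitude * exp(-(t - t_m)/decay_h)` at times `t >= t_m`
#' and 0 before.
#'
#' @param t hours post-dose (vector).
#' @param meal_times_h meal times, hours post-dose.
#' @param amplitude effect at the meal instant.
#' @param decay_h exponential decay constant, h.
#' @return numeric vector, same length as `t`.
#' @export
food_effect <- function(t, meal_times_h, amplitude, decay_h) {
  out <- numeric(length(t))
  for (tm in meal_times_h) {
    on <- t >= tm
    out[on] <- out[on] + amplitude * exp(-(t[on] - tm) / decay_h)
  }
  out
}

#' Simulate triplicate ECG interval measurements for a trial
#'
#' For every subject, period, study day (baseline day -1 and dosing day 1),
#' nominal time and replicate, draws an RR interval around the subject's mean
#' (transiently shortened after meals) and computes the measured QT as
#' `QT = QTc_true * RR^b_i + noise`, where the subject's true QTc combines the
#' baseline level, sex offset, circadian and postprandial terms and a linear
#' drug effect on the time-matched concentration, and `b_i` is the subject's
#' true log-log QT-RR exponent. Meals occur at the design meal times on both
#' study days; concentrations are 0 on day -1 and in placebo periods.
#'
#' @param design a `cqt_design`.
#' @param pk_table concentration table from [simulate_pk()] (parent analyte
#'   rows are used); must cover every subject/period/time of the design.
#' @param qt_params a `cqt_qt_params`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param n_replicates ECG replicates per time point.
#' @return data.frame: subject_id, sequence_id, sex, period, day, treatment,
#'   dose_mg, nominal_time_h, replicate, qt_ms, rr_s.
#' @export
simulate_ecg <- function(design, pk_table, qt_params = qt_model_params(),
                         seed = NULL, n_replicates = 3) {
  stopifnot(inherits(design, "cqt_design"), inherits(qt_params, "cqt_qt_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- qt_params
  subs <- design$subjects
  n <- nrow(subs)
  subj_qtc <- setNames(rnorm(n, p$qtc_pop_mean, p$qtc_between_subject_sd),
                       subs$subject_id)
  subj_b <- setNames(rnorm(n, p$qt_rr_exponent_mean, p$qt_rr_exponent_sd),
                     subs$subject_id)
  subj_rr <- setNames(rnorm(n, p$rr_mean_s, p$rr_between_subject_sd),
                      subs$subject_id)

  tt <- treatment_table(design)
  times <- design$nominal_times_h
  cells <- CJ_df(tt, day = c(-1L, 1L), nominal_time_h = times,
                 replicate = seq_len(n_replicates))

  ## time-matched concentration: day 1 active periods only
  pk <- data.table::as.data.table(pk_table)[analyte == "parent",
    .(subject_id, period, nominal_time_h, conc_ng_ml)]
  dt <- data.table::as.data.table(cells)
  dt <- pk[dt, on = c("subject_id", "period", "nominal_time_h")]
  if (anyNA(dt$conc_ng_ml[dt$day == 1L])) {
    stop("pk_table does not cover all design subject/period/time cells")
  }
  dt[day == -1L, conc_ng_ml := 0]
  dt[is.na(conc_ng_ml), conc_ng_ml := 0]

  food_qtc <- food_effect(dt$nominal_time_h, design$meal_times_h,
                          p$food_effect_amplitude, p$food_effect_decay_h)
  food_rr <- food_effect(dt$nominal_time_h, design$meal_times_h,
                         -p$rr_food_drop_s, p$food_effect_decay_h)
  circ <- p$circadian_amplitude * cos(2 * pi * dt$nominal_time_h / 24)

  rr <- subj_rr[dt$subject_id] + food_rr + rnorm(nrow(dt), 0, p$rr_within_sd)
  rr <- pmax(rr, 0.3)
  qtc_true <- subj_qtc[dt$subject_id] +
    p$sex_effect * (dt$sex == "F") + circ + food_qtc +
    p$drug_slope * dt$conc_ng_ml
  qt <- qtc_true * rr ^ subj_b[dt$subject_id] + rnorm(nrow(dt), 0, p$replicate_sd)

  out <- data.frame(subject_id = dt$subject_id, sequence_id = dt$sequence_id,
                    sex = dt$sex, period = dt$period, day = dt$day,
                    treatment = dt$treatment, dose_mg = dt$dose_mg,
                    nominal_time_h = dt$nominal_time_h,
                    replicate = dt$replicate, qt_ms = qt, rr_s = rr,
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$period, out$day, out$nominal_time_h,
            out$replicate), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

## cross-join a data.frame with extra grid variables (row order deterministic)
CJ_df <- function(df, ...) {
  extra <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  extra <- extra[do.call(order, extra), , drop = FALSE]
  out <- df[rep(seq_len(nrow(df)), each = nrow(extra)), , drop = FALSE]
  out <- cbind(out, extra[rep(seq_len(nrow(extra)), times = nrow(df)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper: builds the design, simulates PK, then triplicate ECGs,
#' all under one seed.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed controlling all randomness.
#' @param qt_params a `cqt_qt_params`.
#' @param pk_params_list named list of `cqt_pk_params` per active treatment.
#' @param iiv_sdlog between-subject PK lognormal SD.
#' @param metabolites simulate metabolite analytes too?
#' @param dropout if `TRUE`, one randomly chosen subject is withdrawn before
#'   their first active period (mirroring a single non-completer).
#' @param ... passed to [build_design()].
#' @return list of class `cqt_trial` with elements `design`, `pk`, `ecg`.
#' @examples
#' trial <- simulate_trial(n_subjects = 8, seed = 1)
#' head(trial$ecg)
#' @export
simulate_trial <- function(n_subjects = 32, seed = 1,
                           qt_params = qt_model_params(),
                           pk_params_list = default_pk_params(),
                           iiv_sdlog = 0.2, metabolites = FALSE,
                           dropout = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- build_design(n_subjects, ...)
  pk <- simulate_pk(design, pk_params_list, seed = NULL, iiv_sdlog = iiv_sdlog,
                    metabolites = metabolites)
  ecg <- simulate_ecg(design, pk, qt_params, seed = NULL)
  if (dropout) {
    drop_id <- sample(design$subjects$subject_id, 1)
    tt <- treatment_table(design)
    first_active <- min(tt$period[tt$subject_id == drop_id & tt$dose_mg > 0])
    keep_ecg <- !(ecg$subject_id == drop_id & ecg$period >= first_active)
    keep_pk <- !(pk$subject_id == drop_id & pk$period >= first_active)
    ecg <- ecg[keep_ecg, ]
    pk <- pk[keep_pk, ]
  }
  structure(list(design = design, pk = pk, ecg = ecg), class = "cqt_trial")
}

#' @export
print.cqt_trial <- function(x, ...) {
  cat("Synthetic crossover trial:", nrow(x$design$subjects), "subjects;",
      nrow(x$ecg), "ECG traces;", nrow(x$pk), "PK samples\n")
  invisible(x)
}

#' Write a simulated trial to CSV files
#'
#' Writes `ecg.csv` (subject_id, sequence, period, day, treatment,
#' nominal_time_h, replicate, qt_ms, rr_s), `pk.csv` (subject_id, period,
#' dose_mg, analyte, nominal_time_h, conc_ng_ml) and `design.csv` (subject_id,
#' sequence, sex, period, treatment, dose_mg).
#'
#' @param trial a `cqt_trial`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_trial_csvs <- function(trial, dir) {
  stopifnot(inherits(trial, "cqt_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ecg <- trial$ecg
  ecg_out <- data.frame(subject_id = ecg$subject_id, sequence = ecg$sequence_id,
                        period = ecg$period, day = ecg$day,
                        treatment = ecg$treatment,
                        nominal_time_h = ecg$nominal_time_h,
                        replicate = ecg$replicate, qt_ms = ecg$qt_ms,
                        rr_s = ecg$rr_s)
  pk_out <- trial$pk[, c("subject_id", "period", "dose_mg", "analyte",
                         "nominal_time_h", "conc_ng_ml")]
  des <- treatment_table(trial$design)
  des_out <- data.frame(subject_id = des$subject_id, sequence = des$sequence_id,
                        sex = des$sex, period = des$period,
                        treatment = des$treatment, dose_mg = des$dose_mg)
  paths <- file.path(dir, c("ecg.csv", "pk.csv", "design.csv"))
  write.csv(ecg_out, paths[1], row.names = FALSE)
  write.csv(pk_out, paths[2], row.names = FALSE)
  write.csv(des_out, paths[3], row.names = FALSE)
  invisible(paths)
}
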