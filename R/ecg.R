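#' Fridericia heart-rate correction
#'
#' `QTcF = QT / RR^exponent` with RR in seconds. The canonical cube-root
#' exponent (1/3) is the default; some reports print the rounded value 0.33,
#' which differs by < 0.5 ms at physiological RR and is available via
#' `exponent = 0.33`.
#'
#' @param qt_ms QT interval, ms.
#' @param rr_s RR interval, seconds (strictly positive).
#' @param exponent power of RR.
#' @return corrected QT, ms.
#' @examples
#' fridericia(400, 1)    # 400
#' fridericia(400, 0.64) # 464.2
#' @export
fridericia <- function(qt_ms, rr_s, exponent = 1 / 3) {
  if (any(!is.na(rr_s) & rr_s <= 0)) stop("rr_s must be strictly positive")
  qt_ms / rr_s ^ exponent
}

## canonical internal ECG column names; accepts `sequence` for `sequence_id`
canonicalise_ecg <- function(records) {
  d <- as.data.frame(records)
  if (!"sequence_id" %in% names(d) && "sequence" %in% names(d)) {
    names(d)[names(d) == "sequence"] <- "sequence_id"
  }
  need <- c("subject_id", "period", "day", "treatment", "nominal_time_h",
            "replicate", "qt_ms", "rr_s")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("ECG table missing columns: ", paste(miss, collapse = ", "))
  if (any(d$qt_ms <= 0, na.rm = TRUE)) stop("qt_ms must be strictly positive")
  d$rr_s <- normalise_rr_seconds(d$rr_s)
  if (any(d$rr_s <= 0, na.rm = TRUE)) stop("rr_s must be strictly positive")
  d
}

#' Reduce replicate ECGs to per-time-point medians
#'
#' Collapses the replicates within each (subject, period, day, treatment,
#' time) cell to the median of each measurement column, each interval reduced
#' independently. With an even number of available replicates the median is
#' the mean of the two central values. The replicate count is retained for QC.
#'
#' @param records replicate-level ECG table (see [simulate_ecg()] for the
#'   canonical columns); any of qt_ms, rr_s, qtcf_ms, qtci_ms present are
#'   reduced.
#' @return data.frame with one row per cell, the median columns, and
#'   `n_replicates`.
#' @export
reduce_triplicates <- function(records) {
  d <- as.data.frame(records)
  keys <- intersect(c("subject_id", "sequence_id", "sex", "period", "day",
                      "treatment", "dose_mg", "nominal_time_h"), names(d))
  vals <- intersect(c("qt_ms", "rr_s", "qtcf_ms", "qtci_ms"), names(d))
  if (!length(vals)) stop("no measurement columns to reduce")
  dt <- data.table::as.data.table(d)
  out <- dt[, c(lapply(.SD, function(v) median(v, na.rm = TRUE)),
                list(n_replicates = .N)),
            by = keys, .SDcols = vals]
  data.table::setorderv(out, intersect(c("subject_id", "period", "day",
                                         "nominal_time_h"), keys))
  as.data.frame(out)
}

## correlation that treats a numerically constant x as perfectly decorrelated
## (an exact correction leaves QTc constant up to float noise; the Pearson r
## of that noise against RR is meaningless)
residual_cor <- function(x, y) {
  s <- sd(x)
  if (is.na(s) || s < 1e-9 * (1 + abs(mean(x)))) return(0)
  cor(x, y)
}

## least-squares fits for one subject's drug-free (QT, RR) pairs
fit_correction_models <- function(subject_id, qt, rr) {
  n <- length(qt)
  out <- vector("list", 2)
  if (sd(rr) < 1e-10) return(NULL)  # degenerate regressor
  ## linear: QT = a + b RR, QTcI = QT - b (RR - 1)
  cf <- lm.fit(cbind(1, rr), qt)$coefficients
  qtci_lin <- qt - cf[2] * (rr - 1)
  out[[1]] <- data.frame(
    subject_id = subject_id, method = "linear",
    slope_or_exponent = unname(cf[2]), intercept = unname(cf[1]),
    residual_corr = residual_cor(qtci_lin, rr),
    qtc_rr_slope = unname(lm.fit(cbind(1, rr), qtci_lin)$coefficients[2]),
    n_points = n, stringsAsFactors = FALSE)
  ## log-log: ln QT = a + b ln RR, QTcI = QT / RR^b
  cfl <- lm.fit(cbind(1, log(rr)), log(qt))$coefficients
  qtci_log <- qt / rr ^ cfl[2]
  out[[2]] <- data.frame(
    subject_id = subject_id, method = "loglog",
    slope_or_exponent = unname(cfl[2]), intercept = unname(cfl[1]),
    residual_corr = residual_cor(qtci_log, rr),
    qtc_rr_slope = unname(lm.fit(cbind(1, rr), qtci_log)$coefficients[2]),
    n_points = n, stringsAsFactors = FALSE)
  rbind(out[[1]], out[[2]])
}

#' Fit per-subject individual heart-rate corrections
#'
#' For each subject, fits the two candidate corrections on the subject's
#' drug-free (QT, RR) pairs by least squares: a linear model
#' `QT = a + b*RR` (QTcI = QT - b(RR - 1)) and a log-log model
#' `ln QT = a + b*ln RR` (QTcI = QT / RR^b). Drug-free points are all
#' baseline-day records of every period plus dosing-day records of the placebo
#' period, at replicate level. Each fit carries the Pearson correlation
#' between its corrected QTc and RR over the fitting data, and the slope of
#' QTc regressed on RR (both feed the selection rule).
#'
#' Subjects with fewer than `n_min` drug-free pairs, or with no RR variation,
#' are flagged with a single `method = "fridericia"` fallback row and a
#' warning.
#'
#' @param records replicate-level ECG table.
#' @param n_min minimum number of drug-free pairs required for fitting.
#' @return data.frame of class `cqt_corrections`: one row per subject and
#'   method with slope_or_exponent, intercept, residual_corr, qtc_rr_slope,
#'   n_points.
#' @export
fit_individual_corrections <- function(records, n_min = 20) {
  d <- canonicalise_ecg(records)
  offdrug <- d$day == -1 | (d$day == 1 & d$treatment == "placebo")
  d <- d[offdrug, ]
  fits <- list()
  fallback <- character()
  for (s in unique(d$subject_id)) {
    di <- d[d$subject_id == s & complete.cases(d[d$subject_id == s,
                                                 c("qt_ms", "rr_s")]), ]
    f <- NULL
    if (nrow(di) >= n_min) f <- fit_correction_models(s, di$qt_ms, di$rr_s)
    if (is.null(f)) {
      fallback <- c(fallback, s)
      f <- data.frame(subject_id = s, method = "fridericia",
                      slope_or_exponent = NA_real_, intercept = NA_real_,
                      residual_corr = NA_real_, qtc_rr_slope = NA_real_,
                      n_points = nrow(di), stringsAsFactors = FALSE)
    }
    fits[[s]] <- f
  }
  if (length(fallback)) {
    warning("falling back to Fridericia for subject(s) with insufficient or ",
            "degenerate drug-free data: ", paste(fallback, collapse = ", "))
  }
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("cqt_corrections", "data.frame")
  out
}

#' Select the best individual correction between a linear and a log-log fit
#'
#' Three-step rule: (1) the model with the smaller absolute Pearson
#' correlation between its QTc and RR wins; (2) on a tie, the model with the
#' smaller absolute slope of the QTc-on-RR regression wins; (3) on a further
#' tie, the log-log model is selected. Ties are compared to an absolute
#' tolerance.
#'
#' @param linear,loglog one-row data.frames as produced by
#'   [fit_individual_corrections()] for the same subject and data.
#' @param tol absolute tie tolerance.
#' @return the selected one-row model.
#' @export
select_correction <- function(linear, loglog, tol = 1e-12) {
  stopifnot(nrow(linear) == 1L, nrow(loglog) == 1L,
            linear$method == "linear", loglog$method == "loglog")
  dr <- abs(linear$residual_corr) - abs(loglog$residual_corr)
  if (dr < -tol) return(linear)
  if (dr > tol) return(loglog)
  ds <- abs(linear$qtc_rr_slope) - abs(loglog$qtc_rr_slope)
  if (ds < -tol) return(linear)
  loglog
}

#' Apply the selection rule to every subject's fitted corrections
#'
#' @param corrections a `cqt_corrections` table.
#' @param tol tie tolerance, see [select_correction()].
#' @return data.frame with the selected row per subject (Fridericia fallback
#'   rows pass through unchanged).
#' @export
select_corrections <- function(corrections, tol = 1e-12) {
  picks <- lapply(split(as.data.frame(corrections), corrections$subject_id),
                  function(cs) {
    if (nrow(cs) == 1L) return(cs)  # fallback
    select_correction(cs[cs$method == "linear", ], cs[cs$method == "loglog", ],
                      tol = tol)
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

## corrected QTc under a selected per-subject model row
apply_correction <- function(qt_ms, rr_s, model_row, fridericia_exponent = 1 / 3) {
  switch(model_row$method,
    linear = qt_ms - model_row$slope_or_exponent * (rr_s - 1),
    loglog = qt_ms / rr_s ^ model_row$slope_or_exponent,
    fridericia = fridericia(qt_ms, rr_s, fridericia_exponent),
    stop("unknown correction method: ", model_row$method))
}

#' Average-baseline QTc per subject and period
#'
#' The baseline is the arithmetic mean, over the baseline-day time points of a
#' period, of the per-time-point median QTc values — one scalar per subject,
#' period and QTc variable. Periods with no baseline-day data are excluded
#' with a warning.
#'
#' @param reduced median-reduced ECG table from [reduce_triplicates()]
#'   containing baseline-day (`day == -1`) rows.
#' @param value_cols QTc columns to average.
#' @return data.frame: subject_id, period, and `baseline_av_<col>` columns.
#' @export
compute_baseline_av <- function(reduced, value_cols = c("qtcf_ms", "qtci_ms")) {
  value_cols <- intersect(value_cols, names(reduced))
  if (!length(value_cols)) stop("no QTc columns found to average")
  base <- reduced[reduced$day == -1, , drop = FALSE]
  all_sp <- unique(reduced[, c("subject_id", "period")])
  if (!nrow(base)) stop("no baseline-day (day == -1) rows present")
  dt <- data.table::as.data.table(base)
  out <- dt[, lapply(.SD, mean), by = c("subject_id", "period"),
            .SDcols = value_cols]
  data.table::setnames(out, value_cols, paste0("baseline_av_", value_cols))
  out <- as.data.frame(out)
  missing_sp <- nrow(all_sp) - nrow(out)
  if (missing_sp > 0) {
    warning(missing_sp, " subject-period(s) have no baseline-day data and are excluded")
  }
  out
}

#' Baseline-corrected and placebo-subtracted QTc changes
#'
#' Computes, per subject, period and dosing-day time point,
#' `dQTc = QTc - baseline_av` and the time-matched double difference
#' `ddQTc(dose, t) = dQTc(dose, t) - dQTc(placebo, t)` for active periods.
#' Cells without a time-matched placebo value stay `NA` (never imputed).
#'
#' @param day1 median-reduced dosing-day (`day == 1`) rows.
#' @param baselines output of [compute_baseline_av()].
#' @return data.frame of per subject/period/time observations with dqtcf_ms /
#'   dqtci_ms and ddqtcf_ms / ddqtci_ms as available.
#' @export
compute_deltas <- function(day1, baselines) {
  d <- data.table::as.data.table(day1)
  b <- data.table::as.data.table(baselines)
  d <- b[d, on = c("subject_id", "period")]
  has_f <- all(c("qtcf_ms", "baseline_av_qtcf_ms") %in% names(d))
  has_i <- all(c("qtci_ms", "baseline_av_qtci_ms") %in% names(d))
  if (has_f) d[, dqtcf_ms := qtcf_ms - baseline_av_qtcf_ms]
  if (has_i) d[, dqtci_ms := qtci_ms - baseline_av_qtci_ms]
  pbo <- d[treatment == "placebo",
           c("subject_id", "nominal_time_h",
             intersect(c("dqtcf_ms", "dqtci_ms"), names(d))),
           with = FALSE]
  data.table::setnames(pbo, c("dqtcf_ms", "dqtci_ms"),
                       c("dqtc_pbo_f", "dqtc_pbo_i"), skip_absent = TRUE)
  d <- pbo[d, on = c("subject_id", "nominal_time_h")]
  if (has_f) d[, ddqtcf_ms := ifelse(treatment == "placebo", NA_real_,
                                     dqtcf_ms - dqtc_pbo_f)]
  if (has_i) d[, ddqtci_ms := ifelse(treatment == "placebo", NA_real_,
                                     dqtci_ms - dqtc_pbo_i)]
  d[, c("dqtc_pbo_f", "dqtc_pbo_i") := NULL]
  no_pbo <- setdiff(unique(d$subject_id), unique(d$subject_id[d$treatment == "placebo"]))
  if (length(no_pbo)) {
    warning("subject(s) without a placebo period; their ddQTc is missing: ",
            paste(no_pbo, collapse = ", "))
  }
  data.table::setorderv(d, c("subject_id", "period", "nominal_time_h"))
  as.data.frame(d)
}

#' Derive the per-time-point QTc observation table from raw ECG and PK data
#'
#' Full reduction pipeline: per-replicate QTcF; per-subject individual
#' correction fitted on drug-free replicates and selected by the three-step
#' rule (QTcI, with Fridericia fallback); median reduction per time point;
#' average baseline per subject-period; dQTc and time-matched placebo
#' double difference ddQTc; time-matched drug concentration (0 in placebo
#' periods).
#'
#' @param ecg replicate-level ECG table (columns as in `ecg.csv`; `sex` is
#'   merged from `design` if not already present).
#' @param pk optional concentration table (as from [simulate_pk()]).
#' @param design optional `cqt_design` or design table supplying `sex` per
#'   subject.
#' @param analyte analyte whose concentrations are time-matched.
#' @param n_min minimum drug-free pairs for an individual correction.
#' @param fridericia_exponent RR power used for QTcF (and fallback QTcI).
#' @return data.frame of class `cqt_observations`, one row per subject,
#'   period and dosing-day time point with qtcf_ms, qtci_ms, baselines,
#'   dqtc/ddqtc columns and conc_ng_ml; the selected correction models are
#'   attached as `attr(, "corrections")`.
#' @examples
#' trial <- simulate_trial(n_subjects = 8, seed = 42)
#' obs <- derive_qtc_observations(trial$ecg, trial$pk)
#' head(obs)
#' @export
derive_qtc_observations <- function(ecg, pk = NULL, design = NULL,
                                    analyte = "parent", n_min = 20,
                                    fridericia_exponent = 1 / 3) {
  d <- canonicalise_ecg(ecg)
  if (!"sex" %in% names(d)) {
    if (is.null(design)) stop("ECG table has no sex column; supply `design`")
    subs <- if (inherits(design, "cqt_design")) design$subjects else
      unique(as.data.frame(design)[, c("subject_id", "sex")])
    d <- merge(d, subs[, c("subject_id", "sex")], by = "subject_id")
  }
  d$qtcf_ms <- fridericia(d$qt_ms, d$rr_s, fridericia_exponent)
  corr_all <- fit_individual_corrections(d, n_min = n_min)
  corr <- select_corrections(corr_all)
  d$qtci_ms <- NA_real_
  for (k in seq_len(nrow(corr))) {
    idx <- d$subject_id == corr$subject_id[k]
    d$qtci_ms[idx] <- apply_correction(d$qt_ms[idx], d$rr_s[idx], corr[k, ],
                                       fridericia_exponent)
  }
  reduced <- reduce_triplicates(d)
  baselines <- compute_baseline_av(reduced)
  day1 <- reduced[reduced$day == 1, , drop = FALSE]
  obs <- compute_deltas(day1, baselines)

  if (!is.null(pk)) {
    pk_df <- as.data.frame(pk)
    pk_df <- pk_df[pk_df$analyte == analyte,
                   c("subject_id", "period", "nominal_time_h", "conc_ng_ml")]
    if (!nrow(pk_df)) stop("no PK rows for analyte '", analyte, "'")
    pk_dt <- data.table::as.data.table(pk_df)
    obs_dt <- data.table::as.data.table(obs)
    obs_dt <- pk_dt[obs_dt, on = c("subject_id", "period", "nominal_time_h")]
    obs_dt[treatment == "placebo" & is.na(conc_ng_ml), conc_ng_ml := 0]
    n_unmatched <- sum(is.na(obs_dt$conc_ng_ml))
    if (n_unmatched) {
      message(n_unmatched, " ECG time point(s) without a matching PK sample; ",
              "left missing")
    }
    obs <- as.data.frame(obs_dt)
  } else {
    obs$conc_ng_ml <- NA_real_
  }
  attr(obs, "corrections") <- corr
  attr(obs, "analyte") <- analyte
  class(obs) <- c("cqt_observations", "data.frame")
  obs
}

#' Read a trial from its CSV files
#'
#' Counterpart of [write_trial_csvs()].
#'
#' @param dir directory containing `ecg.csv`, `pk.csv`, `design.csv`.
#' @return list with `ecg` (sex merged in), `pk`, `design_table`.
#' @export
read_trial_csvs <- function(dir) {
  paths <- file.path(dir, c("ecg.csv", "pk.csv", "design.csv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
  ecg <- read.csv(paths[1], stringsAsFactors = FALSE)
  pk <- read.csv(paths[2], stringsAsFactors = FALSE)
  des <- read.csv(paths[3], stringsAsFactors = FALSE)
  ecg <- merge(ecg, unique(des[, c("subject_id", "sex")]), by = "subject_id")
  list(ecg = ecg, pk = pk, design_table = des)
}
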