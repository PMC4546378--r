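#' Pipeline configuration
#'
#' Collects and validates every setting of the end-to-end analysis. With
#' `input_dir = NULL` the synthetic-trial generator supplies the data;
#' otherwise `ecg.csv`, `pk.csv` and `design.csv` are read from `input_dir`.
#'
#' @param n_subjects subjects to simulate (ignored when reading inputs).
#' @param seed integer seed governing every stochastic stage (mandatory).
#' @param input_dir optional directory with input CSVs.
#' @param qtc_variable corrected QT variable for the time-course and headline
#'   concentration models.
#' @param sensitivity_qtc_variable variable for the assay-sensitivity test.
#' @param analyte analyte for the concentration models.
#' @param timecourse_conf_level CI level of the per-time contrasts.
#' @param slope_conf_level_s1,slope_conf_level_s2 slope CI levels per series.
#' @param prediction_conf_level CI level of Cmax-level predictions.
#' @param bootstrap_B bootstrap replicates.
#' @param bootstrap_trigger_ms |point| above which the bootstrap CI is added.
#' @param sensitivity_times,sensitivity_conf_level,sensitivity_threshold_ms
#'   assay-sensitivity settings.
#' @param fridericia_exponent RR power for QTcF (0.33 mirrors reports that
#'   print the rounded exponent).
#' @param aic_criterion "ml" (default) or "reml" AIC for model selection.
#' @param reference_dose optional fixed dose-normalisation reference, mg.
#' @param timecourse_window_h window for the largest time-matched difference.
#' @param qt_params,pk_params_list,iiv_sdlog,metabolites,dropout generator
#'   settings (see [simulate_trial()]).
#' @return validated list of class `cqt_config`.
#' @export
pipeline_config <- function(n_subjects = 32, seed = 1, input_dir = NULL,
                            qtc_variable = "QTcI",
                            sensitivity_qtc_variable = "QTcF",
                            analyte = "parent",
                            timecourse_conf_level = 0.90,
                            slope_conf_level_s1 = 0.90,
                            slope_conf_level_s2 = 0.95,
                            prediction_conf_level = 0.90,
                            bootstrap_B = 1000,
                            bootstrap_trigger_ms = 5,
                            sensitivity_times = c(6, 8),
                            sensitivity_conf_level = 0.95,
                            sensitivity_threshold_ms = -5,
                            fridericia_exponent = 1 / 3,
                            aic_criterion = "ml",
                            reference_dose = NULL,
                            timecourse_window_h = 24,
                            qt_params = qt_model_params(),
                            pk_params_list = default_pk_params(),
                            iiv_sdlog = 0.2,
                            metabolites = FALSE,
                            dropout = FALSE) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  stopifnot(qtc_variable %in% c("QTcI", "QTcF"),
            sensitivity_qtc_variable %in% c("QTcI", "QTcF"),
            aic_criterion %in% c("ml", "reml"),
            bootstrap_B >= 200)
  cfg <- as.list(environment())
  class(cfg) <- "cqt_config"
  cfg
}

#' Run the full concentration-QTc analysis pipeline
#'
#' Executes the stages in order — data (simulate or load), ECG processing,
#' NCA, per-time-point crossover analysis, both series of concentration-effect
#' models for QTcI and QTcF with AIC selection, Cmax-level predictions (with
#' a bootstrap CI when the point estimate exceeds the trigger), and the
#' meal-based assay-sensitivity test — writing each result table as CSV plus
#' a run log and a machine-readable JSON summary. Reruns with the same
#' configuration and seed reproduce the outputs exactly.
#'
#' @param config a `cqt_config` from [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the result objects and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "cqt_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  ## log lines carry no timestamps so reruns are byte-identical
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- config

  ## -- data -----------------------------------------------------------
  trial <- stage("data", {
    if (!is.null(cfg$input_dir)) {
      note("loading inputs from ", cfg$input_dir)
      inp <- read_trial_csvs(cfg$input_dir)
      list(design = NULL, ecg = inp$ecg, pk = inp$pk)
    } else {
      note("simulating trial: n=", cfg$n_subjects, ", seed=", cfg$seed)
      tr <- simulate_trial(cfg$n_subjects, seed = cfg$seed,
                           qt_params = cfg$qt_params,
                           pk_params_list = cfg$pk_params_list,
                           iiv_sdlog = cfg$iiv_sdlog,
                           metabolites = cfg$metabolites,
                           dropout = cfg$dropout)
      write_trial_csvs(tr, out_dir)
      tr
    }
  })
  note("data: ", nrow(trial$ecg), " ECG rows, ", nrow(trial$pk), " PK rows")

  ## -- ECG processing --------------------------------------------------
  obs <- stage("process", derive_qtc_observations(
    trial$ecg, trial$pk, design = trial$design, analyte = cfg$analyte,
    fridericia_exponent = cfg$fridericia_exponent))
  note("process: ", nrow(obs), " QTc observations (",
       nrow(trial$ecg), " replicates in); ",
       sum(is.na(obs$ddqtci_ms) & obs$dose_mg > 0),
       " active cells without time-matched placebo")
  write.csv(obs, file.path(out_dir, "qtc_observations.csv"), row.names = FALSE)

  ## -- NCA -------------------------------------------------------------
  nca <- stage("nca", nca_table(trial$pk, analyte = cfg$analyte))
  nca_sum <- stage("nca", summarize_dose_group(nca, cfg$reference_dose))
  note("nca: ", nrow(nca), " profiles, ", nrow(nca_sum), " dose groups")
  write.csv(nca, file.path(out_dir, "nca_results.csv"), row.names = FALSE)
  write.csv(nca_sum, file.path(out_dir, "nca_summary.csv"), row.names = FALSE)

  ## -- per-time-point crossover analysis -------------------------------
  tc <- stage("timecourse", fit_timecourse(obs, cfg$qtc_variable,
                                           cfg$timecourse_conf_level))
  largest <- largest_time_matched_difference(tc, cfg$timecourse_window_h)
  note("timecourse: ", nrow(tc$contrasts), " contrasts; largest differences ",
       paste(sprintf("%s: %.2f ms", largest$treatment, largest$estimate_ms),
             collapse = "; "))
  write.csv(tc$contrasts, file.path(out_dir, "timecourse_contrasts.csv"),
            row.names = FALSE)

  ## -- concentration-effect models --------------------------------------
  fits <- stage("concentration_models", {
    out <- list()
    for (qv in c("QTcI", "QTcF")) {
      for (v in 1:3) {
        out[[paste0("s1_", qv, "_v", v)]] <-
          fit_series1(obs, v, qv, cfg$slope_conf_level_s1)
      }
      for (v in 1:2) {
        out[[paste0("s2_", qv, "_v", v)]] <-
          fit_series2(obs, v, qv, cfg$slope_conf_level_s2)
      }
    }
    out
  })
  best <- list()
  fit_rows <- list()
  for (qv in c("QTcI", "QTcF")) {
    for (ser in 1:2) {
      keys <- grep(paste0("^s", ser, "_", qv), names(fits), value = TRUE)
      b <- select_by_aic(fits[keys], cfg$aic_criterion)
      best[[paste0("s", ser, "_", qv)]] <- b
      for (k in keys) {
        f <- fits[[k]]
        fit_rows[[k]] <- data.frame(
          series = f$series, variant = f$variant, qtc_variable = f$qtc_variable,
          analyte = f$analyte, slope = f$slope, ci_low = f$ci_low,
          ci_high = f$ci_high, aic_ml = f$aic_ml, aic_reml = f$aic_reml,
          best_fit = identical(f$variant, b$variant), stringsAsFactors = FALSE)
      }
    }
  }
  model_fits <- do.call(rbind, fit_rows)
  rownames(model_fits) <- NULL
  note("concentration models: ", nrow(model_fits), " fits; best by AIC (",
       cfg$aic_criterion, "): ",
       paste(vapply(names(best), function(k)
         sprintf("%s variant %d", k, best[[k]]$variant), character(1)),
         collapse = "; "))
  write.csv(model_fits, file.path(out_dir, "model_fits.csv"), row.names = FALSE)

  ## -- predictions at the geometric-mean Cmax ---------------------------
  preds <- stage("predictions", {
    rows <- list()
    for (dose in sort(unique(nca$dose_mg))) {
      conc <- geometric_mean_cmax(nca, dose, cfg$analyte)
      for (k in names(best)) {
        b <- best[[k]]
        p <- predict_at_concentration(b, conc, cfg$prediction_conf_level)
        method <- "parametric"
        if (abs(p$point) > cfg$bootstrap_trigger_ms) {
          note("prediction |", round(p$point, 2), "| ms > ",
               cfg$bootstrap_trigger_ms, " ms trigger: bootstrap CI for ",
               k, " at ", dose, " mg")
          p <- bootstrap_prediction_ci(obs, nca, dose, series = b$series,
                                       variant = b$variant,
                                       qtc_variable = b$qtc_variable,
                                       B = cfg$bootstrap_B, seed = cfg$seed,
                                       conf_level = cfg$prediction_conf_level)
          method <- "bootstrap"
        }
        rows[[paste(k, dose)]] <- data.frame(
          series = b$series, variant = b$variant,
          qtc_variable = b$qtc_variable, dose_mg = dose,
          concentration_ng_ml = conc, point_ms = p$point,
          ci_low = p$ci_low, ci_high = p$ci_high,
          ci_level = cfg$prediction_conf_level, method = method,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  rownames(preds) <- NULL
  write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  note("predictions: ", nrow(preds), " dose-by-model predictions")

  ## -- assay sensitivity -------------------------------------------------
  sens <- stage("assay_sensitivity", assay_sensitivity(
    obs, qtc_variable = cfg$sensitivity_qtc_variable,
    times = cfg$sensitivity_times, conf_level = cfg$sensitivity_conf_level,
    threshold_ms = cfg$sensitivity_threshold_ms,
    aic_criterion = cfg$aic_criterion))
  sens_out <- cbind(sens$contrasts, criterion_met = sens$criterion_met)
  write.csv(sens_out, file.path(out_dir, "assay_sensitivity.csv"),
            row.names = FALSE)
  note("assay sensitivity: criterion ",
       if (sens$criterion_met) "MET" else "NOT met")

  ## -- log + summary ------------------------------------------------------
  summary_list <- list(
    seed = cfg$seed,
    n_subjects = length(unique(obs$subject_id)),
    qtc_variable = cfg$qtc_variable,
    largest_time_matched_difference = largest,
    best_fits = lapply(best, function(b)
      list(series = b$series, variant = b$variant,
           qtc_variable = b$qtc_variable, slope = b$slope,
           ci = c(b$ci_low, b$ci_high), aic_ml = b$aic_ml,
           aic_reml = b$aic_reml)),
    predictions = preds,
    assay_sensitivity = list(contrasts = as.data.frame(sens$contrasts),
                             criterion_met = sens$criterion_met)
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(observations = obs, nca = nca, nca_summary = nca_sum,
                 timecourse = tc, largest = largest, fits = fits,
                 best = best, predictions = preds, sensitivity = sens,
                 out_dir = out_dir))
}
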