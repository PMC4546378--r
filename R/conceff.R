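## internal constructor for a fitted (or externally supplied) C-QT model
new_cqt_fit <- function(series, variant, qtc_variable, analyte, slope,
                        slope_se, df, conf_level, aic_ml = NA_real_,
                        aic_reml = NA_real_, n_varpar = NA_real_,
                        n_obs = NA_integer_, n_subjects = NA_integer_,
                        model = NULL, beta = NULL, V = NULL, c0 = NULL,
                        conc_name = NULL, conc_scale = 1,
                        time_levels = NULL, intercept = NA_real_) {
  ci <- if (is.na(slope_se)) c(NA_real_, NA_real_) else
    t_interval(slope, slope_se, df, conf_level)
  structure(list(series = series, variant = variant,
                 qtc_variable = qtc_variable, analyte = analyte,
                 slope = slope, slope_se = slope_se, df = df,
                 conf_level = conf_level, ci_low = ci[1], ci_high = ci[2],
                 aic_ml = aic_ml, aic_reml = aic_reml, n_varpar = n_varpar,
                 n_obs = n_obs, n_subjects = n_subjects, model = model,
                 beta = beta, V = V, c0 = c0, conc_name = conc_name,
                 conc_scale = conc_scale, time_levels = time_levels,
                 intercept = intercept),
            class = "cqt_fit")
}

#' @export
print.cqt_fit <- function(x, ...) {
  cat("C-QT mixed model: series ", x$series, ", variant ", x$variant, ", ",
      x$qtc_variable, ", analyte ", x$analyte, "\n", sep = "")
  cat(sprintf("  slope %.5g ms/(ng/mL)  [%d%% CI %.5g, %.5g]\n",
              x$slope, round(100 * x$conf_level), x$ci_low, x$ci_high))
  cat(sprintf("  AIC (ML) %.1f, AIC (REML) %.1f, n = %s obs / %s subjects\n",
              x$aic_ml, x$aic_reml, x$n_obs, x$n_subjects))
  invisible(x)
}

#' Construct a concentration-effect fit from published quantities
#'
#' Builds a minimal `cqt_fit` from an externally reported slope (for example a
#' printed model table) so [predict_at_concentration()] and [select_by_aic()]
#' can be applied to published results.
#'
#' @param slope concentration slope, ms per ng/mL.
#' @param slope_se its standard error (optional; `NA` gives point predictions
#'   without intervals).
#' @param series 1 (placebo-subtracted ddQTc models) or 2 (change-from-baseline
#'   models with time as factor).
#' @param variant model variant within the series.
#' @param intercept fixed intercept (series-1 variants 1-2 only).
#' @param df degrees of freedom for t intervals.
#' @param conf_level slope CI level.
#' @param aic_ml,aic_reml optional information criteria.
#' @param qtc_variable,analyte labels.
#' @return a `cqt_fit`.
#' @examples
#' f <- conc_effect_fit(slope = -0.00079, series = 2)
#' predict_at_concentration(f, 5464.0)
#' @export
conc_effect_fit <- function(slope, slope_se = NA_real_, series = 2,
                            variant = 1, intercept = 0, df = Inf,
                            conf_level = 0.90, aic_ml = NA_real_,
                            aic_reml = NA_real_, qtc_variable = "QTcI",
                            analyte = "parent") {
  n_varpar <- if (series == 1 && variant == 3) 4 else if (variant == 2) 4 else 2
  new_cqt_fit(series = series, variant = variant, qtc_variable = qtc_variable,
              analyte = analyte, slope = slope, slope_se = slope_se, df = df,
              conf_level = conf_level, aic_ml = aic_ml, aic_reml = aic_reml,
              n_varpar = n_varpar, intercept = intercept)
}

## REML fit + optional ML refit of a concentration-effect lme; the
## concentration covariate is rescaled to ug/mL internally so random-slope
## variances are well scaled, and the slope is reported back per ng/mL
fit_conc_lme <- function(d, fixed, random, ml_aic) {
  m <- nlme::lme(fixed, random = random, data = d, method = "REML",
                 control = lme_control())
  aic_reml <- AIC(m)
  aic_ml <- NA_real_
  if (ml_aic) {
    m_ml <- nlme::lme(fixed, random = random, data = d, method = "ML",
                      control = lme_control())
    aic_ml <- AIC(m_ml)
  }
  list(m = m, aic_reml = aic_reml, aic_ml = aic_ml)
}

CONC_SCALE <- 1000  # ng/mL -> ug/mL for fitting

#' Series-1 concentration-effect model (placebo-subtracted ddQTc)
#'
#' REML linear mixed model for the time-matched placebo-subtracted change of
#' QTc from average baseline (ddQTc) against the time-matched analyte plasma
#' concentration, on active periods. Variants: 1 — period, sequence and sex as
#' fixed effects plus concentration, random intercepts; 2 — as 1 plus a
#' random concentration slope; 3 — no fixed effects, fixed intercept
#' constrained to 0, random intercept and slope.
#'
#' All variants carry nested random intercepts for subject and
#' subject-by-period: the change-from-baseline values of one period share
#' that period's baseline-average measurement error, and the nested intercept
#' is the compound-symmetry covariance for such within-period repeated
#' measures. Random slopes are at the subject level.
#'
#' @param obs a `cqt_observations` table with ddQTc and matched concentrations.
#' @param variant 1, 2 or 3.
#' @param qtc_variable which corrected QT to analyse.
#' @param conf_level two-sided slope CI level.
#' @param ml_aic also refit by ML to obtain a comparable AIC (default); set
#'   `FALSE` to skip the refit when AICs are not needed.
#' @return a `cqt_fit`.
#' @export
fit_series1 <- function(obs, variant = 1, qtc_variable = c("QTcI", "QTcF"),
                        conf_level = 0.90, ml_aic = TRUE) {
  qtc_variable <- match.arg(qtc_variable)
  stopifnot(variant %in% 1:3)
  d <- prep_model_data(obs, qtc_variable)
  d <- drop_unused_levels(d[d$dose_mg > 0 & !is.na(d$dd) & !is.na(d$conc_ng_ml), ])
  if (!nrow(d)) stop("no active-period rows with ddQTc and concentration")
  if (all(d$conc_ng_ml == 0)) stop("all concentrations are zero")
  d$conc_u <- d$conc_ng_ml / CONC_SCALE
  d$y <- d$dd
  if (variant %in% 1:2) {
    fixed <- y ~ period + sequence_f + sex + conc_u
    random <- if (variant == 1) list(subject_id = ~ 1, period = ~ 1) else
      list(subject_id = ~ 1 + conc_u, period = ~ 1)
  } else {
    fixed <- y ~ 0 + conc_u
    random <- list(subject_id = ~ 1 + conc_u, period = ~ 1)
  }
  X <- model.matrix(fixed, d)
  rank_X <- check_full_rank(X)
  fit <- fit_conc_lme(d, fixed, random, ml_aic)
  beta <- nlme::fixef(fit$m)
  V <- vcov(fit$m)
  df <- nrow(d) - rank_X
  slope <- unname(beta["conc_u"]) / CONC_SCALE
  slope_se <- sqrt(V["conc_u", "conc_u"]) / CONC_SCALE
  c0 <- colMeans(X)
  c0["conc_u"] <- 0
  new_cqt_fit(series = 1, variant = variant, qtc_variable = qtc_variable,
              analyte = attr(obs, "analyte") %||% "parent", slope = slope,
              slope_se = slope_se, df = df, conf_level = conf_level,
              aic_ml = fit$aic_ml, aic_reml = fit$aic_reml,
              n_varpar = if (variant == 1) 3 else 5, n_obs = nrow(d),
              n_subjects = length(unique(d$subject_id)), model = fit$m,
              beta = beta, V = V, c0 = c0, conc_name = "conc_u",
              conc_scale = CONC_SCALE,
              intercept = if (variant == 3) 0 else unname(sum(c0 * beta)))
}

#' Series-2 concentration-effect model (change from baseline with time factor)
#'
#' REML linear mixed model for the change of QTc from average baseline (dQTc),
#' without placebo subtraction: placebo periods enter the fit with
#' concentration 0, and nominal time enters as a categorical fixed effect so
#' the spontaneous (meal-driven, circadian) time course is estimated from all
#' periods and the concentration slope is corrected for it. Variants: 1 —
#' time, period, sequence and sex as fixed factors plus concentration, random
#' intercepts; 2 — as 1 plus a random concentration slope. As in
#' [fit_series1()], nested subject and subject-by-period random intercepts
#' realise the compound-symmetry covariance of within-period repeated
#' measures.
#'
#' @inheritParams fit_series1
#' @param variant 1 or 2.
#' @param allow_no_placebo proceed (with a warning) when no placebo rows are
#'   present; by default this is an error since the time course is then
#'   confounded with the drug effect.
#' @return a `cqt_fit`; the estimated time effects (vs pre-dose) are available
#'   via [postprandial_contrasts()].
#' @export
fit_series2 <- function(obs, variant = 1, qtc_variable = c("QTcI", "QTcF"),
                        conf_level = 0.95, ml_aic = TRUE,
                        allow_no_placebo = FALSE) {
  qtc_variable <- match.arg(qtc_variable)
  stopifnot(variant %in% 1:2)
  d <- prep_model_data(obs, qtc_variable)
  d <- drop_unused_levels(d[!is.na(d$y) & !is.na(d$conc_ng_ml), ])
  if (!nrow(d)) stop("no rows with dQTc and concentration")
  if (!any(d$dose_mg == 0)) {
    if (!allow_no_placebo) stop("no placebo rows present; the time course is ",
                                "unidentifiable from active periods alone")
    warning("no placebo rows; time effects are confounded with the drug effect")
  }
  if (all(d$conc_ng_ml == 0)) {
    stop("all concentrations are zero; no concentration effect is estimable")
  }
  d$conc_u <- d$conc_ng_ml / CONC_SCALE
  fixed <- y ~ time_f + period + sequence_f + sex + conc_u
  random <- if (variant == 1) list(subject_id = ~ 1, period = ~ 1) else
    list(subject_id = ~ 1 + conc_u, period = ~ 1)
  X <- model.matrix(fixed, d)
  rank_X <- check_full_rank(X)
  fit <- fit_conc_lme(d, fixed, random, ml_aic)
  beta <- nlme::fixef(fit$m)
  V <- vcov(fit$m)
  df <- nrow(d) - rank_X
  slope <- unname(beta["conc_u"]) / CONC_SCALE
  slope_se <- sqrt(V["conc_u", "conc_u"]) / CONC_SCALE
  new_cqt_fit(series = 2, variant = variant, qtc_variable = qtc_variable,
              analyte = attr(obs, "analyte") %||% "parent", slope = slope,
              slope_se = slope_se, df = df, conf_level = conf_level,
              aic_ml = fit$aic_ml, aic_reml = fit$aic_reml,
              n_varpar = if (variant == 1) 3 else 5, n_obs = nrow(d),
              n_subjects = length(unique(d$subject_id)), model = fit$m,
              beta = beta, V = V, conc_name = "conc_u",
              conc_scale = CONC_SCALE,
              time_levels = levels(d$time_f))
}

#' Select the best concentration-effect model by AIC
#'
#' Returns the fit with the smallest AIC. By default the AIC from maximum
#' likelihood refits is compared (REML criteria are not comparable across
#' different fixed-effect structures); `criterion = "reml"` compares the REML
#' values instead. Exact ties go to the model with the fewest variance
#' parameters, then the lowest variant number.
#'
#' @param fits list of `cqt_fit` objects from the same series and data.
#' @param criterion "ml" or "reml".
#' @return the winning `cqt_fit`, with the full AIC comparison attached as
#'   `attr(, "aic_table")`.
#' @export
select_by_aic <- function(fits, criterion = c("ml", "reml")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("empty fit list")
  if (inherits(fits, "cqt_fit")) fits <- list(fits)
  aic <- vapply(fits, function(f) {
    a <- if (criterion == "ml") f$aic_ml else f$aic_reml
    if (is.na(a)) stop("fit has no ", toupper(criterion), " AIC")
    a
  }, numeric(1))
  nvp <- vapply(fits, function(f) f$n_varpar %||% NA_real_, numeric(1))
  variant <- vapply(fits, function(f) f$variant, numeric(1))
  ord <- order(aic, nvp, variant)
  best <- fits[[ord[1]]]
  tab <- data.frame(
    series = vapply(fits, function(f) f$series, numeric(1)),
    variant = variant,
    qtc_variable = vapply(fits, function(f) f$qtc_variable, character(1)),
    slope = vapply(fits, function(f) f$slope, numeric(1)),
    aic_ml = vapply(fits, function(f) f$aic_ml, numeric(1)),
    aic_reml = vapply(fits, function(f) f$aic_reml, numeric(1)),
    best_fit = seq_along(fits) == ord[1])
  attr(best, "aic_table") <- tab
  best
}

#' Geometric mean of individual observed Cmax for a dose group
#'
#' @param nca_results NCA table ([nca_table()]).
#' @param dose_mg dose group, mg.
#' @param analyte analyte label.
#' @return geometric mean Cmax in ng/mL; the number of subjects excluded for a
#'   missing Cmax is attached as `attr(, "n_missing")`.
#' @export
geometric_mean_cmax <- function(nca_results, dose_mg, analyte = "parent") {
  d <- as.data.frame(nca_results)
  d <- d[d$dose_mg == dose_mg & d$analyte == analyte, ]
  if (!nrow(d)) stop("no NCA results for dose ", dose_mg, " mg / ", analyte)
  n_missing <- sum(is.na(d$cmax))
  cmax <- d$cmax[!is.na(d$cmax)]
  if (!length(cmax)) stop("no non-missing Cmax values")
  if (any(cmax <= 0)) stop("Cmax values must be strictly positive")
  out <- geometric_mean(cmax)
  attr(out, "n_missing") <- n_missing
  out
}

#' Predict the QTc effect at a plasma concentration
#'
#' For series-2 models and the series-1 zero-intercept variant the prediction
#' is `slope * concentration`: between two otherwise identical subjects, one
#' exposed and one not, every time and covariate term cancels. For series-1
#' variants 1-2 the fixed intercept contributes: the prediction is the mean
#' fixed-effect value at concentration 0 over the estimation data plus
#' `slope * concentration`. Confidence intervals are two-sided t intervals on
#' the corresponding fixed-effect linear combination.
#'
#' @param fit a `cqt_fit`.
#' @param concentration plasma concentration, ng/mL (nonnegative).
#' @param conf_level CI level.
#' @return object of class `cqt_prediction`: list with `point`, `ci_low`,
#'   `ci_high` (ms), `concentration`, `conf_level`, `method`.
#' @examples
#' predict_at_concentration(conc_effect_fit(-0.00079, series = 2), 5464.0)
#' @export
predict_at_concentration <- function(fit, concentration, conf_level = 0.90) {
  stopifnot(inherits(fit, "cqt_fit"))
  if (concentration < 0) stop("concentration must be nonnegative")
  slope_only <- fit$series == 2 || (fit$series == 1 && fit$variant == 3)
  if (slope_only) {
    point <- fit$slope * concentration
    se <- fit$slope_se * concentration
  } else if (!is.null(fit$c0) && !is.null(fit$V)) {
    cvec <- fit$c0
    cvec[fit$conc_name] <- concentration / fit$conc_scale
    point <- unname(sum(cvec * fit$beta))
    se <- sqrt(drop(t(cvec) %*% fit$V %*% cvec))
  } else {
    point <- (fit$intercept %||% 0) + fit$slope * concentration
    se <- fit$slope_se * concentration  # intercept uncertainty unavailable
  }
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    t_interval(point, se, fit$df, conf_level)
  structure(list(point = point, ci_low = ci[1], ci_high = ci[2],
                 concentration = concentration, conf_level = conf_level,
                 series = fit$series, variant = fit$variant,
                 qtc_variable = fit$qtc_variable, method = "parametric"),
            class = "cqt_prediction")
}

#' @export
print.cqt_prediction <- function(x, ...) {
  cat(sprintf("Predicted %s effect at %.1f ng/mL: %.2f ms [%d%% CI %.2f, %.2f] (%s)\n",
              x$qtc_variable, x$concentration, x$point,
              round(100 * x$conf_level), x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Bootstrap confidence interval for the predicted effect at the mean Cmax
#'
#' Subject-level bootstrap (resampling with replacement, stratified by
#' treatment sequence) that accounts for the sampling variability of the
#' geometric-mean Cmax: each replicate recomputes the geometric-mean Cmax of
#' the resampled subjects AND refits the concentration-effect model before
#' predicting. The interval is the percentile interval over replicates.
#' This is the interval the analysis plan calls for when the parametric point
#' estimate exceeds 5 ms in magnitude; it can also be requested directly.
#'
#' @param obs a `cqt_observations` table.
#' @param nca_results NCA table for the same trial.
#' @param dose_mg dose group whose geometric-mean Cmax is the prediction
#'   concentration.
#' @param series,variant,qtc_variable model specification to refit.
#' @param B number of bootstrap replicates (at least 200).
#' @param seed integer seed.
#' @param conf_level CI level.
#' @return a `cqt_prediction` with `method = "bootstrap"`; the number of
#'   non-convergent replicates dropped is in `n_dropped`.
#' @export
bootstrap_prediction_ci <- function(obs, nca_results, dose_mg, series = 2,
                                    variant = 2,
                                    qtc_variable = c("QTcI", "QTcF"),
                                    B = 1000, seed = NULL, conf_level = 0.90) {
  qtc_variable <- match.arg(qtc_variable)
  stopifnot(B >= 200)
  if (!is.null(seed)) set.seed(seed)
  obs <- as.data.frame(obs)
  nca <- as.data.frame(nca_results)
  subs <- unique(obs[, c("subject_id", "sequence_id")])
  if (nrow(subs) < 5) stop("need at least 5 subjects to bootstrap")
  fit_fun <- function(o) {
    o <- structure(o, class = c("cqt_observations", "data.frame"))
    if (series == 1) fit_series1(o, variant, qtc_variable, ml_aic = FALSE)
    else fit_series2(o, variant, qtc_variable, ml_aic = FALSE)
  }
  base_fit <- fit_fun(obs)
  base_conc <- geometric_mean_cmax(nca, dose_mg)
  base_point <- predict_at_concentration(base_fit, base_conc, conf_level)$point

  obs_by <- split(obs, obs$subject_id)
  nca_by <- split(nca, nca$subject_id)
  strata <- split(subs$subject_id, subs$sequence_id)
  points <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    picked <- unlist(lapply(strata, function(ids)
      ids[sample.int(length(ids), length(ids), replace = TRUE)]),
      use.names = FALSE)
    ob <- do.call(rbind, obs_by[picked])
    nb <- do.call(rbind, nca_by[picked])
    new_ids <- sprintf("B%03d", seq_along(picked))
    reps_o <- vapply(obs_by[picked], nrow, integer(1))
    reps_n <- vapply(nca_by[picked], nrow, integer(1))
    ob$subject_id <- rep(new_ids, reps_o)
    nb$subject_id <- rep(new_ids, reps_n)
    points[b] <- tryCatch({
      fb <- fit_fun(ob)
      cb <- geometric_mean_cmax(nb, dose_mg)
      predict_at_concentration(fb, cb, conf_level)$point
    }, error = function(e) NA_real_)
  }
  ok <- points[!is.na(points)]
  n_dropped <- B - length(ok)
  if (n_dropped > 0.1 * B) {
    warning(n_dropped, " of ", B, " bootstrap replicates failed to converge")
  }
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(ok, c(a, 1 - a)))
  structure(list(point = base_point, ci_low = ci[1], ci_high = ci[2],
                 concentration = base_conc, conf_level = conf_level,
                 series = series, variant = variant,
                 qtc_variable = qtc_variable, method = "bootstrap",
                 B = B, n_dropped = n_dropped),
            class = "cqt_prediction")
}
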