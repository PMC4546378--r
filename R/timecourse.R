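## shared factor coding for the mixed models: placebo / pre-dose reference,
## treatments ordered by dose, baseline covariate centred at its grand mean
prep_model_data <- function(obs, qtc_variable = c("QTcI", "QTcF")) {
  qtc_variable <- match.arg(qtc_variable)
  d <- as.data.frame(obs)
  ycol <- if (qtc_variable == "QTcI") "dqtci_ms" else "dqtcf_ms"
  ddcol <- if (qtc_variable == "QTcI") "ddqtci_ms" else "ddqtcf_ms"
  bcol <- if (qtc_variable == "QTcI") "baseline_av_qtci_ms" else "baseline_av_qtcf_ms"
  stopifnot(ycol %in% names(d))
  d$y <- d[[ycol]]
  d$dd <- if (ddcol %in% names(d)) d[[ddcol]] else NA_real_
  d$baseline_c <- d[[bcol]] - mean(d[[bcol]], na.rm = TRUE)
  trts <- unique(d[, c("treatment", "dose_mg")])
  trts <- trts[order(trts$dose_mg), ]
  d$treatment <- factor(d$treatment, levels = trts$treatment)
  d$period <- factor(d$period)
  d$sequence_f <- factor(d$sequence_id)
  d$sex <- factor(d$sex)
  tl <- sort(unique(d$nominal_time_h))
  d$time_f <- factor(d$nominal_time_h, levels = tl)
  d
}

## drop unused factor levels after row filtering so the design stays full rank
drop_unused_levels <- function(d) {
  for (col in c("treatment", "period", "sequence_f", "sex", "time_f")) {
    if (col %in% names(d)) d[[col]] <- droplevels(d[[col]])
  }
  d
}

## stop with the aliased columns named if the fixed design is rank-deficient
check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  qrX$rank
}

lme_control <- function() {
  nlme::lmeControl(opt = "optim", maxIter = 300, msMaxIter = 300,
                   niterEM = 50, returnObject = TRUE)
}

#' Per-time-point crossover mixed model of baseline-corrected QTc
#'
#' Fits, by REML, the primary analysis model
#' `dQTc ~ sequence + period + sex + treatment * time + baseline` with a
#' random intercept per subject (the induced covariance is compound symmetry),
#' time as a categorical factor with the pre-dose level as reference, and the
#' subject-period average baseline (grand-mean centred) as covariate. The
#' dose-minus-placebo contrast and its two-sided t-based confidence interval
#' are derived at every post-dose time point.
#'
#' @param obs a `cqt_observations` table ([derive_qtc_observations()]).
#' @param qtc_variable which corrected QT to analyse.
#' @param conf_level two-sided confidence level for the contrasts.
#' @return object of class `cqt_timecourse`: list with `contrasts`
#'   (data.frame: treatment, dose_mg, time_h, estimate_ms, se, ci_low,
#'   ci_high), the fitted `model`, `df` used for the t intervals,
#'   `qtc_variable` and `conf_level`.
#' @export
fit_timecourse <- function(obs, qtc_variable = c("QTcI", "QTcF"),
                           conf_level = 0.90) {
  qtc_variable <- match.arg(qtc_variable)
  d <- prep_model_data(obs, qtc_variable)
  d <- drop_unused_levels(d[complete.cases(d[, c("y", "baseline_c")]), ])
  if (length(unique(d$treatment)) < 2L || length(unique(d$subject_id)) < 2L) {
    stop("need at least two treatments and two subjects")
  }
  fixed <- y ~ sequence_f + period + sex + treatment * time_f + baseline_c
  X <- model.matrix(fixed, d)
  rank_X <- check_full_rank(X)
  m <- nlme::lme(fixed, random = ~ 1 | subject_id, data = d,
                 method = "REML", control = lme_control())
  beta <- nlme::fixef(m)
  V <- vcov(m)
  df <- nrow(d) - rank_X

  trts <- levels(d$treatment)[-1]  # active doses (placebo is reference)
  times <- levels(d$time_f)[-1]    # post-dose (pre-dose is reference)
  doses <- unique(d[, c("treatment", "dose_mg")])
  rows <- list()
  for (trt in trts) {
    for (tv in times) {
      cvec <- setNames(numeric(length(beta)), names(beta))
      cvec[paste0("treatment", trt)] <- 1
      int_name <- paste0("treatment", trt, ":time_f", tv)
      if (int_name %in% names(beta)) cvec[int_name] <- 1
      est <- sum(cvec * beta)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      ci <- t_interval(est, se, df, conf_level)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = trt, dose_mg = doses$dose_mg[doses$treatment == trt],
        time_h = as.numeric(tv), estimate_ms = est, se = se,
        ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)
  contrasts <- contrasts[order(contrasts$dose_mg, contrasts$time_h), ]
  rownames(contrasts) <- NULL
  structure(list(contrasts = contrasts, model = m, df = df,
                 qtc_variable = qtc_variable, conf_level = conf_level),
            class = "cqt_timecourse")
}

#' @export
print.cqt_timecourse <- function(x, ...) {
  cat("Per-time-point crossover analysis of d", x$qtc_variable, " (",
      round(100 * x$conf_level), "% CIs, t df = ", x$df, ")\n", sep = "")
  print(head(x$contrasts, 12), digits = 3)
  if (nrow(x$contrasts) > 12) cat("... (", nrow(x$contrasts), " contrasts)\n")
  invisible(x)
}

#' Largest time-matched difference to placebo per dose
#'
#' For each dose, the post-dose contrast (within a time window) with the
#' maximal point estimate. Exact ties go to the earliest time.
#'
#' @param fit a `cqt_timecourse`.
#' @param window_h upper bound (hours) of the post-dose window searched.
#' @return data.frame: treatment, dose_mg, time_h, estimate_ms, ci_low,
#'   ci_high.
#' @export
largest_time_matched_difference <- function(fit, window_h = 24) {
  stopifnot(inherits(fit, "cqt_timecourse"))
  ct <- fit$contrasts
  ct <- ct[ct$time_h > 0 & ct$time_h <= window_h, ]
  out <- lapply(split(ct, ct$treatment), function(g) {
    g <- g[order(g$time_h), ]
    g[which.max(g$estimate_ms), ]  # first max -> earliest time on ties
  })
  out <- do.call(rbind, out)
  out <- out[order(out$dose_mg), c("treatment", "dose_mg", "time_h",
                                   "estimate_ms", "ci_low", "ci_high")]
  rownames(out) <- NULL
  out
}
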