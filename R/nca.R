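## AUC of one segment by the linear-up/log-down rule
auc_segment <- function(t1, t2, c1, c2, method = "linuplogdown") {
  dt <- t2 - t1
  if (method == "linear" || c2 >= c1 || c1 <= 0 || c2 <= 0) {
    return(dt * (c1 + c2) / 2)
  }
  dt * (c1 - c2) / log(c1 / c2)
}

## concentration interpolated at time t0 within (t1, t2); log interpolation on
## a strictly declining positive segment, linear otherwise
interp_conc <- function(t0, t1, t2, c1, c2, method = "linuplogdown") {
  f <- (t0 - t1) / (t2 - t1)
  if (method == "linear" || c2 >= c1 || c1 <= 0 || c2 <= 0) {
    return(c1 + f * (c2 - c1))
  }
  exp(log(c1) + f * (log(c2) - log(c1)))
}

#' Non-compartmental analysis of one concentration-time profile
#'
#' Derives Cmax and tmax by direct maximum (ties to the earliest time),
#' AUC0-t to the last quantifiable concentration by the linear-up/log-down
#' trapezoid (linear trapezoid available via `method = "linear"`), AUC0-24
#' by the same rule with interpolation at 24 h when needed, the terminal
#' log-linear slope lambda_z by the best adjusted-R-squared regression over
#' candidate tails of 3-8 quantifiable points strictly after tmax,
#' `t1/2 = ln 2 / lambda_z`, and `AUC0-inf = AUC0-t + Clast / lambda_z`.
#' When no acceptable terminal fit exists (fewer than 3 eligible points or a
#' non-declining tail), t1/2 and AUC0-inf are `NA` and the result is flagged.
#'
#' @param time_h sampling times, hours, strictly increasing.
#' @param conc concentrations, ng/mL; values below the limit of
#'   quantification should be 0 before tmax and `NA` after.
#' @param dose_mg dose administered, mg (carried through).
#' @param method trapezoid rule: "linuplogdown" (default) or "linear".
#' @param lambda_tail_range candidate terminal tail sizes.
#' @return list of class `cqt_nca`: cmax, tmax, t_half, auc_0_t, auc_0_24,
#'   auc_0_inf, lambda_z, n_lambda_points, r2_adj, t_last, flags.
#' @examples
#' run_nca(c(0, 1, 2), c(0, 10, 5))$auc_0_t # 5 + 5/log(2)
#' @export
run_nca <- function(time_h, conc, dose_mg = NA_real_,
                    method = c("linuplogdown", "linear"),
                    lambda_tail_range = 3:8) {
  method <- match.arg(method)
  keep <- !is.na(conc)
  time_h <- time_h[keep]; conc <- conc[keep]
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (sum(conc[time_h > 0] > 0) < 2) {
    stop("need at least 2 positive post-dose concentrations")
  }
  cmax <- max(conc)
  tmax <- time_h[which.max(conc)]  # earliest time on ties

  i_last <- max(which(conc > 0))
  t_last <- time_h[i_last]
  auc_0_t <- 0
  for (i in seq_len(i_last - 1)) {
    auc_0_t <- auc_0_t + auc_segment(time_h[i], time_h[i + 1],
                                     conc[i], conc[i + 1], method)
  }

  auc_0_24 <- NA_real_
  if (t_last >= 24) {
    auc_0_24 <- 0
    for (i in seq_len(length(time_h) - 1)) {
      t1 <- time_h[i]; t2 <- time_h[i + 1]
      if (t2 <= 24) {
        auc_0_24 <- auc_0_24 + auc_segment(t1, t2, conc[i], conc[i + 1], method)
      } else if (t1 < 24) {
        c24 <- interp_conc(24, t1, t2, conc[i], conc[i + 1], method)
        auc_0_24 <- auc_0_24 + auc_segment(t1, 24, conc[i], c24, method)
      }
      if (t2 >= 24) break
    }
  }

  ## terminal slope over candidate tails strictly after tmax
  elig <- which(time_h > tmax & conc > 0)
  best <- NULL
  for (k in lambda_tail_range) {
    if (length(elig) < k) break
    idx <- utils::tail(elig, k)
    y <- log(conc[idx])
    ft <- lm.fit(cbind(1, time_h[idx]), y)
    sl <- ft$coefficients[2]
    if (is.na(sl) || sl >= 0) next
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(ft$residuals^2) / sst else 1
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2a > best$r2a) {
      best <- list(lambda = -unname(sl), n = k, r2a = r2a)
    }
  }
  flags <- character()
  if (is.null(best)) {
    lambda_z <- NA_real_; t_half <- NA_real_; auc_0_inf <- NA_real_
    n_lambda <- 0L; r2_adj <- NA_real_
    flags <- "no_terminal_fit"
  } else {
    lambda_z <- best$lambda
    t_half <- log(2) / lambda_z
    auc_0_inf <- auc_0_t + conc[i_last] / lambda_z
    n_lambda <- best$n
    r2_adj <- best$r2a
  }
  structure(list(cmax = cmax, tmax = tmax, t_half = t_half,
                 auc_0_t = auc_0_t, auc_0_24 = auc_0_24,
                 auc_0_inf = auc_0_inf, lambda_z = lambda_z,
                 n_lambda_points = n_lambda, r2_adj = r2_adj,
                 t_last = t_last, dose_mg = dose_mg, flags = flags),
            class = "cqt_nca")
}

#' @export
print.cqt_nca <- function(x, ...) {
  cat(sprintf("NCA: Cmax %.4g at %.2f h; t1/2 %.3g h; AUC0-t %.5g; AUC0-inf %.5g\n",
              x$cmax, x$tmax, x$t_half, x$auc_0_t, x$auc_0_inf))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' NCA for every subject-period profile of a concentration table
#'
#' @param pk concentration table (as from [simulate_pk()] or `pk.csv`).
#' @param analyte analyte to analyse.
#' @param ... passed to [run_nca()].
#' @return data.frame: subject_id, period, dose_mg, analyte and the NCA
#'   parameters, one row per active subject-period.
#' @export
nca_table <- function(pk, analyte = "parent", ...) {
  d <- as.data.frame(pk)
  d <- d[d$analyte == analyte & d$dose_mg > 0, ]
  if (!nrow(d)) stop("no active-dose rows for analyte '", analyte, "'")
  d <- d[order(d$subject_id, d$period, d$nominal_time_h), ]
  keys <- unique(d[, c("subject_id", "period", "dose_mg")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    di <- d[d$subject_id == keys$subject_id[i] & d$period == keys$period[i], ]
    r <- tryCatch(run_nca(di$nominal_time_h, di$conc_ng_ml,
                          dose_mg = keys$dose_mg[i], ...),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(subject_id = keys$subject_id[i], period = keys$period[i],
               dose_mg = keys$dose_mg[i], analyte = analyte,
               cmax = r$cmax, tmax = r$tmax, t_half = r$t_half,
               auc_0_t = r$auc_0_t, auc_0_24 = r$auc_0_24,
               auc_0_inf = r$auc_0_inf, lambda_z = r$lambda_z,
               n_lambda_points = r$n_lambda_points, r2_adj = r$r2_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dose-group summary of NCA parameters
#'
#' Arithmetic mean (SD) for Cmax, t1/2 and the AUCs; median (SD) for tmax;
#' geometric-mean Cmax carried separately for effect predictions; and
#' dose-normalised Cmax and AUC0-24 columns. By default each dose group is
#' normalised by its own dose; `reference_dose` normalises all groups by a
#' fixed reference instead. Single-subject groups report SD = 0 and are
#' flagged via `n`.
#'
#' @param nca_results table from [nca_table()].
#' @param reference_dose optional fixed normalisation dose, mg.
#' @return data.frame with one row per dose group.
#' @export
summarize_dose_group <- function(nca_results, reference_dose = NULL) {
  d <- as.data.frame(nca_results)
  if (!nrow(d)) stop("empty NCA table")
  sd0 <- function(x) if (sum(!is.na(x)) < 2) 0 else sd(x, na.rm = TRUE)
  mn <- function(x) mean(x, na.rm = TRUE)
  rows <- lapply(split(d, d$dose_mg), function(g) {
    dose <- g$dose_mg[1]
    data.frame(
      dose_mg = dose, n = nrow(g),
      cmax_mean = mn(g$cmax), cmax_sd = sd0(g$cmax),
      cmax_geomean = geometric_mean(g$cmax),
      tmax_median = median(g$tmax, na.rm = TRUE), tmax_sd = sd0(g$tmax),
      t_half_mean = mn(g$t_half), t_half_sd = sd0(g$t_half),
      auc_0_t_mean = mn(g$auc_0_t), auc_0_t_sd = sd0(g$auc_0_t),
      auc_0_24_mean = mn(g$auc_0_24), auc_0_24_sd = sd0(g$auc_0_24),
      auc_0_inf_mean = mn(g$auc_0_inf), auc_0_inf_sd = sd0(g$auc_0_inf),
      cmax_dose_norm = dose_normalise(mn(g$cmax), dose, reference_dose),
      auc_0_24_dose_norm = dose_normalise(mn(g$auc_0_24), dose, reference_dose))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dose_mg), ]
  rownames(out) <- NULL
  out
}
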