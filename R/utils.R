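`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x numeric vector of strictly positive values; `NA`s are removed.
#' @return `exp(mean(log(x)))`.
#' @examples
#' geometric_mean(c(1, 100)) # 10
#' @export
geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing values")
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Dose-normalise a pharmacokinetic summary value
#'
#' Divides an exposure metric (Cmax, AUC) by the dose. By default each value is
#' normalised by its own dose; `reference_dose` normalises every row by a fixed
#' reference dose instead (some reports normalise all dose groups to the lowest
#' dose studied).
#'
#' @param x numeric exposure value(s).
#' @param dose_mg dose in mg for each value.
#' @param reference_dose optional single reference dose in mg.
#' @return `x / dose` (or `x / reference_dose`).
#' @examples
#' dose_normalise(3938.5, 500) # 7.877
#' @export
dose_normalise <- function(x, dose_mg, reference_dose = NULL) {
  if (!is.null(reference_dose)) {
    stopifnot(length(reference_dose) == 1L, reference_dose > 0)
    return(x / reference_dose)
  }
  if (any(dose_mg <= 0)) stop("dose_mg must be strictly positive")
  x / dose_mg
}

## two-sided t interval for an estimate with standard error `se`
t_interval <- function(estimate, se, df, conf_level) {
  a <- (1 - conf_level) / 2
  q <- stats::qt(1 - a, df = df)
  c(estimate - q * se, estimate + q * se)
}

## normalise an RR column to seconds: values > 10 are taken to be milliseconds
normalise_rr_seconds <- function(rr) {
  ms <- !is.na(rr) & rr > 10
  if (any(ms)) {
    message(sum(ms), " RR values > 10 interpreted as milliseconds and converted to seconds")
    rr[ms] <- rr[ms] / 1000
  }
  rr
}
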