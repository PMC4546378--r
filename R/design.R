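#' Default treatment sequences of the four-period single-ascending-dose design
#'
#' Four sequences over four periods in which single ascending doses (500, 600,
#' 800 mg) or placebo are given; each sequence contains every treatment exactly
#' once and the set balances period and preceding treatment for the placebo
#' position.
#'
#' @return character matrix, one row per sequence, one column per period.
#' @export
default_sequences <- function() {
  m <- rbind(
    c("placebo", "500 mg", "600 mg", "800 mg"),
    c("500 mg", "placebo", "600 mg", "800 mg"),
    c("500 mg", "600 mg", "placebo", "800 mg"),
    c("500 mg", "600 mg", "800 mg", "placebo")
  )
  dimnames(m) <- list(paste0("seq", 1:4), paste0("period", 1:4))
  m
}

#' Default nominal ECG / PK sampling times (hours post-dose)
#'
#' Pre-dose plus 18 post-dose time points out to 96 h, used on the dosing day
#' and (as clock-matched times) on the baseline day.
#'
#' @return numeric vector of hours, strictly increasing, starting at 0.
#' @export
default_nominal_times <- function() {
  c(0, 0.25, 0.5, 0.75, 1.0, 1.25, 1.5, 1.75, 2.0,
    3.0, 4.0, 5.0, 6.0, 8.0, 12, 24, 48, 72, 96)
}

treatment_doses <- c("placebo" = 0, "500 mg" = 500, "600 mg" = 600, "800 mg" = 800)

#' Build a crossover trial design
#'
#' Allocates subjects round-robin to the four treatment sequences (so group
#' sizes differ by at most one) and alternates sex M/F along the subject list.
#' Meals (lunch, dinner) are scheduled at fixed hours post-dose on every study
#' day.
#'
#' @param n_subjects number of subjects (at least 4, one per sequence).
#' @param seed optional integer seed; the default allocation is deterministic,
#'   the seed is kept for interface symmetry with the simulators.
#' @param sequences treatment-sequence matrix as from [default_sequences()].
#' @param nominal_times_h sampling times in hours post-dose; must be strictly
#'   increasing and include 0 (pre-dose).
#' @param washout_days washout between period doses, days.
#' @param meal_times_h hours post-dose of the standardised lunch and dinner.
#' @return an object of class `cqt_design`: a list with `subjects`
#'   (data.frame: subject_id, sequence_id, sex), `sequences`,
#'   `nominal_times_h`, `washout_days`, `meal_times_h`.
#' @examples
#' d <- build_design(32)
#' table(d$subjects$sequence_id)
#' @export
build_design <- function(n_subjects = 32, seed = NULL,
                         sequences = default_sequences(),
                         nominal_times_h = default_nominal_times(),
                         washout_days = 7,
                         meal_times_h = c(5, 9)) {
  if (n_subjects < nrow(sequences)) {
    stop("n_subjects must be at least ", nrow(sequences),
         " (one subject per sequence)")
  }
  stopifnot(is.matrix(sequences), ncol(sequences) == 4L)
  for (i in seq_len(nrow(sequences))) {
    if (!setequal(sequences[i, ], names(treatment_doses))) {
      stop("each sequence must contain each treatment exactly once")
    }
  }
  if (any(diff(nominal_times_h) <= 0) || nominal_times_h[1] != 0) {
    stop("nominal_times_h must be strictly increasing and start at 0")
  }
  sequence_id <- rep_len(seq_len(nrow(sequences)), n_subjects)
  ## alternate sex within each sequence group (not along subject order, which
  ## would make sex a deterministic function of the sequence and alias the
  ## two factors in the crossover models)
  sex <- character(n_subjects)
  sex[order(sequence_id)] <- rep_len(c("M", "F"), n_subjects)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    sequence_id = sequence_id,
    sex = sex,
    stringsAsFactors = FALSE
  )
  structure(
    list(subjects = subjects, sequences = sequences,
         nominal_times_h = nominal_times_h, washout_days = washout_days,
         meal_times_h = meal_times_h),
    class = "cqt_design"
  )
}

#' @export
print.cqt_design <- function(x, ...) {
  cat("Crossover trial design:", nrow(x$subjects), "subjects,",
      nrow(x$sequences), "sequences,", ncol(x$sequences), "periods\n")
  cat("Sequence allocation:",
      paste(table(x$subjects$sequence_id), collapse = "/"),
      " sex:", paste(table(x$subjects$sex)[c("M", "F")], collapse = "M/"), "F\n")
  cat("ECG/PK times (h):", paste(x$nominal_times_h, collapse = ", "), "\n")
  cat("Meals at", paste(x$meal_times_h, collapse = " and "), "h post-dose;",
      "washout", x$washout_days, "days\n")
  invisible(x)
}

#' Long subject-by-period treatment table for a design
#'
#' @param design a `cqt_design`.
#' @return data.frame with subject_id, sequence_id, sex, period, treatment,
#'   dose_mg — one row per subject and period.
#' @export
treatment_table <- function(design) {
  stopifnot(inherits(design, "cqt_design"))
  s <- design$subjects
  n_per <- ncol(design$sequences)
  out <- s[rep(seq_len(nrow(s)), each = n_per), ]
  out$period <- rep(seq_len(n_per), nrow(s))
  out$treatment <- design$sequences[cbind(out$sequence_id, out$period)]
  out$dose_mg <- unname(treatment_doses[out$treatment])
  rownames(out) <- NULL
  out
}
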