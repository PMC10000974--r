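#' Truncate CTC counts entering models as continuous covariates
#'
#' Counts greater than `cap` (default 40) are truncated to `cap`.  Applied
#' only where the count enters a model as a continuous covariate; raw counts
#' are kept everywhere else.
#'
#' @param ctc_count Non-negative integer vector.
#' @param cap Truncation cap (default 40).
#' @return Integer vector in `[0, cap]`.
#' @examples
#' truncate_count(c(0, 40, 5000))  # 0, 40, 40
#' @export
truncate_count <- function(ctc_count, cap = 40) {
  if (any(!is.na(ctc_count) & ctc_count < 0)) stop("CTC counts must be >= 0")
  pmin(ctc_count, cap)
}

#' Dichotomize a CTC count at a cutoff
#'
#' `high` means count at or above the cutoff (the >= 5 convention is
#' inclusive: a count of exactly 5 is high at the default cutoff).
#'
#' @param ctc_count Non-negative integer vector.
#' @param cutoff Integer cutoff >= 1 (default 5).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(ctc_count, cutoff = 5) {
  stopifnot(cutoff >= 1)
  if (any(!is.na(ctc_count) & ctc_count < 0)) stop("CTC counts must be >= 0")
  factor(ifelse(ctc_count >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Clearance of CTCs between two observations
#'
#' `any_to_zero`: cleared when any CTCs at baseline (> 0) resolve to 0.
#' `five_to_subfive`: cleared when >= 5 CTCs at baseline resolve to < 5.
#' Baselines that do not qualify (or missing follow-ups) are `not_applicable`.
#'
#' @param baseline_count,followup_count Counts at baseline and a later visit.
#' @param mode `"any_to_zero"` or `"five_to_subfive"`.
#' @return Factor with levels `cleared`, `not_cleared`, `not_applicable`.
#' @export
clearance_status <- function(baseline_count, followup_count,
                             mode = c("any_to_zero", "five_to_subfive")) {
  mode <- match.arg(mode)
  qualifies <- if (mode == "any_to_zero") baseline_count > 0 else baseline_count >= 5
  cleared <- if (mode == "any_to_zero") followup_count == 0 else followup_count < 5
  out <- ifelse(is.na(baseline_count) | !qualifies | is.na(followup_count),
                "not_applicable",
                ifelse(cleared, "cleared", "not_cleared"))
  factor(out, levels = c("cleared", "not_cleared", "not_applicable"))
}

#' Lead time from first high CTC count to documented progression
#'
#' For each patient with a visit at or above the cutoff and an observed
#' progression, the lead time is the months from the first qualifying visit to
#' the first documented progression.  Negative values (progression recorded
#' before the qualifying visit) are reported as such; patients without an
#' observed progression are returned with `NA` and excluded from summaries.
#'
#' @param visits Data.frame with `patient_id`, `visit`, `months`, `ctc_count`.
#' @param endpoints A `ctc_endpoints` object (see [as_endpoints()]).
#' @param cutoff CTC cutoff (default 5).
#' @param at_visit Optionally restrict the qualifying visit to this visit
#'   number (e.g. 2 for the first follow-up).
#' @return Data.frame `patient_id`, `qualifying_month`, `progression_month`,
#'   `lead_time` (months).
#' @export
lead_time <- function(visits, endpoints, cutoff = 5, at_visit = NULL) {
  stopifnot(inherits(endpoints, "ctc_endpoints"))
  v <- visits[visits$ctc_count >= cutoff, ]
  if (!is.null(at_visit)) v <- v[v$visit %in% at_visit, ]
  if (!nrow(v)) {
    return(data.frame(patient_id = character(), qualifying_month = numeric(),
                      progression_month = numeric(), lead_time = numeric()))
  }
  qual <- stats::aggregate(months ~ patient_id, data = v, FUN = min)
  names(qual)[2] <- "qualifying_month"
  first <- endpoints$first
  out <- merge(qual, first[c("patient_id", "ttp", "progression_observed")],
               by = "patient_id")
  out$progression_month <- ifelse(out$progression_observed, out$ttp, NA_real_)
  out$lead_time <- out$progression_month - out$qualifying_month
  out[c("patient_id", "qualifying_month", "progression_month", "lead_time")]
}

#' Sweep candidate CTC cutoffs against a survival endpoint
#'
#' For each candidate cutoff `c`, patients are stratified by count >= `c` at
#' the chosen visit and a univariate Cox proportional-hazards model of the
#' endpoint on the indicator is fitted, alongside Kaplan-Meier median survival
#' per stratum.  A landmark convention is used: survival is measured from the
#' visit's sample time and patients with an event (or censoring) before that
#' time are excluded.  The "optimal" cutoff is the one maximizing the hazard
#' ratio among cutoffs with at least `min_high` patients in the high group,
#' with ties broken toward the smallest cutoff; the full sweep table is
#' returned so other selection rules can be applied.
#'
#' @param visits Data.frame with `patient_id`, `visit`, `months`, `ctc_count`.
#' @param endpoints A `ctc_endpoints` object.
#' @param cutoffs Integer vector of candidate cutoffs (default 1:10).
#' @param visit Visit whose counts are swept (default 2, the 3-month
#'   follow-up).
#' @param endpoint `"progression"` (PFS; death without progression counts as
#'   progression) or `"death"` (OS).
#' @param min_high Minimum size of the high group for cutoff selection
#'   (default 5).
#' @return Data.frame of class `ctc_sweep`: one row per cutoff with `n_high`,
#'   `n_low`, `events`, `median_high`, `median_low`, `hr`, `lower`, `upper`,
#'   `p`, `optimal`.  Cutoffs with an empty stratum keep their row with
#'   missing HR.
#' @export
cutoff_sweep <- function(visits, endpoints, cutoffs = 1:10, visit = 2,
                         endpoint = c("progression", "death"), min_high = 5) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(endpoints, "ctc_endpoints"))
  obs <- visits[visits$visit == visit, ]
  first <- endpoints$first
  d <- merge(obs[c("patient_id", "months", "ctc_count")], first, by = "patient_id")
  if (endpoint == "progression") {
    d$time <- d$ttp - d$months; d$event <- as.integer(d$progression_observed)
  } else {
    d$time <- d$os_time - d$months; d$event <- as.integer(d$death_observed)
  }
  d <- d[d$time > 0, ]                                   # landmark: event-free at the visit
  rows <- lapply(cutoffs, function(cc) {
    d$high <- as.integer(d$ctc_count >= cc)
    n_high <- sum(d$high == 1); n_low <- sum(d$high == 0)
    row <- data.frame(cutoff = cc, n_high = n_high, n_low = n_low,
                      events = sum(d$event), median_high = NA_real_,
                      median_low = NA_real_, hr = NA_real_, lower = NA_real_,
                      upper = NA_real_, p = NA_real_)
    if (n_high == 0 || n_low == 0 || sum(d$event) == 0) return(row)
    km <- survival::survfit(survival::Surv(time, event) ~ high, data = d)
    med <- summary(km)$table[, "median"]
    row$median_low <- unname(med[grepl("high=0", names(med))])
    row$median_high <- unname(med[grepl("high=1", names(med))])
    fit <- try(cox_fit(d, covariates = "high"), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      tt <- fit$terms
      row$hr <- tt$hr; row$lower <- tt$lower; row$upper <- tt$upper; row$p <- tt$p
    }
    row
  })
  out <- do.call(rbind, rows)
  eligible <- !is.na(out$hr) & out$n_high >= min_high
  out$optimal <- FALSE
  if (any(eligible)) {
    best <- which(eligible)[which.max(out$hr[eligible])]   # which.max: first max = smallest cutoff
    out$optimal[best] <- TRUE
  }
  attr(out, "endpoint") <- endpoint
  attr(out, "visit") <- visit
  class(out) <- c("ctc_sweep", "data.frame")
  out
}
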