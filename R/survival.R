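#' Assemble patient survival endpoints
#'
#' Builds the canonical endpoint object used by the survival machinery.
#' Time is measured in months from the enrollment consent date.  A patient
#' who dies without a prior recorded progression is considered to have
#' progressed on the date of death: an imputed progression event is added at
#' the death time.
#'
#' @param patients Data.frame with `patient_id`, `follow_up` (months of
#'   follow-up, i.e. time of death or censoring), `death_observed` (logical).
#' @param progressions Data.frame with `patient_id`, `time` (months of each
#'   documented progression event; may be empty).
#' @return An object of class `ctc_endpoints`: a list with `patients`,
#'   `progressions` (imputation applied, ordered) and `first` (per-patient
#'   first-event summary: `ttp`, `progression_observed`, `os_time`,
#'   `death_observed`).
#' @export
as_endpoints <- function(patients, progressions = NULL) {
  need <- c("patient_id", "follow_up", "death_observed")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("missing columns in `patients`: ", paste(miss, collapse = ", "))
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient_id rows")
  if (any(patients$follow_up <= 0)) stop("follow-up times must be strictly positive")
  if (is.null(progressions)) {
    progressions <- data.frame(patient_id = character(), time = numeric())
  }
  progressions <- progressions[c("patient_id", "time")]
  unknown <- setdiff(progressions$patient_id, patients$patient_id)
  if (length(unknown)) stop("progression events for unknown patients: ",
                            paste(unique(unknown), collapse = ", "))
  fu <- stats::setNames(patients$follow_up, patients$patient_id)
  if (any(progressions$time <= 0) ||
      any(progressions$time > fu[progressions$patient_id] + 1e-9)) {
    stop("progression times must lie in (0, follow_up]")
  }
  progressions <- progressions[order(progressions$patient_id, progressions$time), ]
  key <- paste(progressions$patient_id, progressions$time)
  if (anyDuplicated(key)) stop("tied progression times within a patient")

  # death without prior progression: impute progression at the death time
  has_prog <- patients$patient_id %in% progressions$patient_id
  imp <- patients[patients$death_observed & !has_prog, ]
  if (nrow(imp)) {
    progressions <- rbind(progressions,
                          data.frame(patient_id = imp$patient_id, time = imp$follow_up))
    progressions <- progressions[order(progressions$patient_id, progressions$time), ]
  }
  rownames(progressions) <- NULL

  first_time <- tapply(progressions$time, progressions$patient_id, min)
  first <- data.frame(patient_id = patients$patient_id,
                      os_time = patients$follow_up,
                      death_observed = patients$death_observed,
                      stringsAsFactors = FALSE)
  first$progression_observed <- first$patient_id %in% progressions$patient_id
  first$ttp <- ifelse(first$progression_observed,
                      as.numeric(first_time[first$patient_id]), first$os_time)
  structure(list(patients = patients, progressions = progressions,
                 first = first[c("patient_id", "ttp", "progression_observed",
                                 "os_time", "death_observed")]),
            class = "ctc_endpoints")
}

#' Kaplan-Meier product-limit fit
#'
#' Product-limit estimate with Greenwood variance and log-log confidence
#' intervals; the median is the first time the estimated survivor function
#' drops to 0.5 or below, with its confidence interval.  All censored means
#' an undefined (missing) median.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Optional grouping factor.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `ctc_km` with `curve` (tidy data.frame: `group`,
#'   `time`, `n_risk`, `n_event`, `estimate`, `lower`, `upper`), `median`
#'   (per group: `median`, `lower`, `upper`) and the underlying `survfit`.
#' @export
km_fit <- function(time, event, group = NULL, conf_level = 0.95) {
  if (any(time <= 0)) stop("times must be strictly positive")
  d <- data.frame(time = time, event = as.integer(event))
  if (is.null(group)) d$group <- "all" else d$group <- as.character(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d,
                           conf.type = "log-log", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  curve <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                      n_event = s$n.event, estimate = s$surv,
                      lower = s$lower, upper = s$upper)
  q <- stats::quantile(fit, probs = 0.5)
  qq <- rbind(q$quantile); ql <- rbind(q$lower); qu <- rbind(q$upper)
  med <- data.frame(group = if (is.null(rownames(qq))) "all" else
                      sub("^group=", "", rownames(qq)),
                    median = qq[, 1], lower = ql[, 1], upper = qu[, 1],
                    row.names = NULL)
  structure(list(curve = curve, median = med, fit = fit), class = "ctc_km")
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by maximum Breslow partial likelihood (Newton-Raphson,
#' as implemented in \pkg{survival}), on either simple `(time, event)` data
#' or left-truncated counting-process `(start, stop]` rows, with optional
#' stratification and a robust sandwich variance clustered on patient.
#'
#' @param data Data.frame holding the outcome and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names for simple survival data.
#' @param start,stop Column names for counting-process data; when `start` is
#'   given, `stop` and `event` delimit each row and `time` is ignored.
#' @param strata Optional column name: stratum-specific baseline hazards.
#' @param cluster Optional column name: robust sandwich variance with
#'   clustering on this id.
#' @param robust Use the robust sandwich variance (default: whenever
#'   `cluster` is given).
#' @param ties `"breslow"` (default, matching SAS PHREG) or `"efron"`.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @return List of class `ctc_coxfit`: `terms` (per covariate: `term`,
#'   `coef`, `se`, `hr`, `lower`, `upper`, `p`), `n`, `nevents`, `loglik`,
#'   `variance` (`"model"` or `"robust_sandwich"`), and the `coxph` fit.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    start = NULL, stop = NULL, strata = NULL, cluster = NULL,
                    robust = !is.null(cluster), ties = c("breslow", "efron"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  for (cov in covariates) {
    v <- data[[cov]]
    if (is.null(v)) stop("covariate column not found: ", cov)
    if (length(unique(v[!is.na(v)])) < 2) {
      stop(sprintf("covariate '%s' is constant; cannot be fitted", cov))
    }
  }
  if (sum(data[[event]] != 0) < 1) stop("no events in the data")
  lhs <- if (is.null(start)) sprintf("survival::Surv(%s, %s)", time, event)
         else sprintf("survival::Surv(%s, %s, %s)", start, stop, event)
  rhs <- c(covariates,
           if (!is.null(strata)) sprintf("survival::strata(%s)", strata),
           if (!is.null(cluster)) sprintf("survival::cluster(%s)", cluster))
  f <- stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties, robust = robust,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        stop("Cox fit failed (possible monotone likelihood / separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (anyNA(co)) stop("singular fit; inestimable covariates: ",
                      paste(names(co)[is.na(co)], collapse = ", "))
  if (any(abs(co) >= 15)) stop("monotone partial likelihood (separation) for: ",
                               paste(names(co)[abs(co) >= 15], collapse = ", "))
  s <- summary(fit, conf.int = conf_level)
  se <- if (robust) s$coefficients[, "robust se"] else s$coefficients[, "se(coef)"]
  z <- co / se
  terms <- data.frame(term = names(co), coef = unname(co), se = unname(se),
                      hr = unname(exp(co)),
                      lower = unname(exp(co - stats::qnorm(1 - (1 - conf_level) / 2) * se)),
                      upper = unname(exp(co + stats::qnorm(1 - (1 - conf_level) / 2) * se)),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(terms = terms, n = fit$n, nevents = fit$nevent,
                 loglik = unname(fit$loglik[length(fit$loglik)]),
                 variance = if (robust) "robust_sandwich" else "model",
                 ties = ties, conf_level = conf_level, fit = fit),
            class = "ctc_coxfit")
}

#' @export
print.ctc_coxfit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties, %s variance): n = %d, events = %d\n",
              x$ties, x$variance, x$n, x$nevents))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Build a counting-process table with LVCF time-dependent covariates
#'
#' Splits each patient's follow-up at covariate measurement times, carrying
#' the last measured value forward (LVCF) from its own time until the next
#' measurement; the interval before the first measurement uses that first
#' (baseline) measurement.  The continuous CTC-count column, when present, is
#' truncated at `cap` before entering the table.  In `recurrent_pwp` mode the
#' follow-up is additionally split at every progression event on the total
#' time scale (time zero at consent for every row), and each row carries an
#' event-number stratum equal to 1 + the number of prior progression events.
#' A covariate measured exactly at an event time takes effect just after it:
#' the event row keeps the preceding interval's value.
#'
#' @param endpoints A `ctc_endpoints` object.
#' @param measurements Data.frame with `patient_id`, `time` (months) and one
#'   column per covariate.
#' @param covariates Covariate columns to carry (default: all columns other
#'   than `patient_id` and `time`).
#' @param mode `"single_event"` (one terminating event) or `"recurrent_pwp"`
#'   (all progression events, PWP total-time layout).
#' @param outcome For `single_event` mode: `"progression"` (first progression,
#'   with death imputed as progression) or `"death"`.
#' @param count_col Name of the continuous CTC count column to truncate
#'   (default `"ctc_count"`, ignored if absent).
#' @param cap Truncation cap (default 40).
#' @return Data.frame of class `ctc_cptable`: `patient_id`, `start`, `stop`,
#'   `event`, `stratum`, covariate columns.  Patients with no usable
#'   measurements are excluded and listed in attribute `excluded`.
#' @export
build_counting_process <- function(endpoints, measurements, covariates = NULL,
                                   mode = c("single_event", "recurrent_pwp"),
                                   outcome = c("progression", "death"),
                                   count_col = "ctc_count", cap = 40) {
  mode <- match.arg(mode); outcome <- match.arg(outcome)
  stopifnot(inherits(endpoints, "ctc_endpoints"))
  if (is.null(covariates)) {
    covariates <- setdiff(names(measurements), c("patient_id", "time"))
  }
  first <- endpoints$first
  prog <- endpoints$progressions
  n_late <- 0L; excluded <- character()
  out <- vector("list", nrow(first))
  for (i in seq_len(nrow(first))) {
    pid <- first$patient_id[i]
    if (mode == "single_event") {
      if (outcome == "progression") {
        T_end <- first$ttp[i]
        ev_times <- if (first$progression_observed[i]) T_end else numeric()
      } else {
        T_end <- first$os_time[i]
        ev_times <- if (first$death_observed[i]) T_end else numeric()
      }
    } else {
      T_end <- first$os_time[i]
      ev_times <- prog$time[prog$patient_id == pid]
    }
    mm <- measurements[measurements$patient_id == pid, , drop = FALSE]
    mm <- mm[order(mm$time), , drop = FALSE]
    late <- mm$time >= T_end & mm$time > 0
    n_late <- n_late + sum(late)
    mm <- mm[!late, , drop = FALSE]
    if (!nrow(mm)) { excluded <- c(excluded, pid); next }
    mm$time[1] <- 0                       # first available measurement applies from consent
    breaks <- sort(unique(c(0, mm$time, ev_times, T_end)))
    breaks <- breaks[breaks <= T_end]
    st <- breaks[-length(breaks)]; sp <- breaks[-1]
    idx <- findInterval(st, mm$time)      # last measurement at or before interval start
    rows <- data.frame(patient_id = pid, start = st, stop = sp,
                       event = as.integer(sp %in% ev_times),
                       stratum = 1L + vapply(st, function(a) sum(ev_times <= a), 0L),
                       stringsAsFactors = FALSE)
    for (cov in covariates) rows[[cov]] <- mm[[cov]][idx]
    out[[i]] <- rows
  }
  if (n_late > 0) {
    warning(sprintf("%d measurement(s) at or after the end of follow-up ignored", n_late))
  }
  if (length(excluded)) {
    message("patients excluded (no usable measurements): ",
            paste(excluded, collapse = ", "))
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(tab) <- NULL
  if (count_col %in% covariates) tab[[count_col]] <- truncate_count(tab[[count_col]], cap)
  if (mode == "single_event") tab$stratum <- 1L
  attr(tab, "mode") <- mode
  attr(tab, "outcome") <- if (mode == "single_event") outcome else "progression"
  attr(tab, "excluded") <- excluded
  class(tab) <- c("ctc_cptable", "data.frame")
  tab
}

#' Prentice-Williams-Peterson recurrent-event fit
#'
#' Cox model on a recurrent-mode counting-process table, stratified on the
#' event-number stratum (stratum-specific baseline hazards on the total time
#' scale) with a robust sandwich variance clustered on patient.  Strata
#' containing no events are dropped with a warning.
#'
#' @param table A `ctc_cptable` built with `mode = "recurrent_pwp"`.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level (default 0.95).
#' @param ties Tie handling (default Breslow).
#' @return A `ctc_coxfit` (robust sandwich variance).
#' @export
pwp_fit <- function(table, covariates, conf_level = 0.95,
                    ties = c("breslow", "efron")) {
  if (!identical(attr(table, "mode"), "recurrent_pwp")) {
    stop("`table` must be built with build_counting_process(mode = \"recurrent_pwp\")")
  }
  ev_per <- tapply(table$event, table$stratum, sum)
  dead <- as.integer(names(ev_per)[ev_per == 0])
  if (length(dead)) {
    warning("dropping event-number strata with no events: ",
            paste(dead, collapse = ", "))
    table <- table[!table$stratum %in% dead, ]
  }
  cox_fit(as.data.frame(table), covariates, start = "start", stop = "stop",
          event = "event", strata = "stratum", cluster = "patient_id",
          robust = TRUE, ties = match.arg(ties), conf_level = conf_level)
}

#' Nelson estimator of the mean cumulative function for recurrent events
#'
#' `MCF(t) = sum over event times s <= t of d(s) / n(s)`, where `d(s)` is the
#' number of events at `s` and `n(s)` the number of subjects still under
#' observation (not yet censored or dead) at `s`.  Computed separately per
#' group (e.g. baseline CTC < 5 vs >= 5).
#'
#' @param events Data.frame with `patient_id`, `time` (one row per recurrent
#'   event).
#' @param followup Data.frame with `patient_id`, `time`: end of observation
#'   for every subject, including subjects with no events.
#' @param group Optional data.frame `patient_id`, `group`.
#' @return Data.frame of class `ctc_mcf`: `group`, `time`, `n_risk`,
#'   `n_events`, `mcf` (step-function values at event times).
#' @export
nelson_mcf <- function(events, followup, group = NULL) {
  if (anyDuplicated(followup$patient_id)) stop("one follow-up row per subject required")
  unknown <- setdiff(events$patient_id, followup$patient_id)
  if (length(unknown)) stop("events for subjects without follow-up: ",
                            paste(unique(unknown), collapse = ", "))
  fu <- stats::setNames(followup$time, followup$patient_id)
  if (any(events$time > fu[events$patient_id] + 1e-9)) {
    stop("event times must not exceed the subject's follow-up time")
  }
  if (is.null(group)) {
    group <- data.frame(patient_id = followup$patient_id, group = "all")
  }
  g <- stats::setNames(as.character(group$group), group$patient_id)
  out <- lapply(sort(unique(g)), function(gg) {
    ids <- names(g)[g == gg]
    ev <- events[events$patient_id %in% ids, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    times <- sort(unique(ev$time))
    d <- vapply(times, function(s) sum(ev$time == s), 0)
    n <- vapply(times, function(s) sum(fu[ids] >= s), 0)
    data.frame(group = gg, time = times, n_risk = n, n_events = d,
               mcf = cumsum(d / n))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(group = character(), time = numeric(), n_risk = numeric(),
                      n_events = numeric(), mcf = numeric())
  }
  rownames(out) <- NULL
  class(out) <- c("ctc_mcf", "data.frame")
  out
}

#' Incidence rate per 100 person-years with exact Poisson interval
#'
#' `rate = 100 * events / person_years`; the confidence interval comes from
#' the exact Poisson (chi-square) bounds on the event count.  With zero
#' events the lower bound is 0 (one-sided interval).
#'
#' @param events Number of events (non-negative integer).
#' @param person_years Person-years at risk (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Data.frame `events`, `person_years`, `rate`, `lower`, `upper`
#'   (all rates per 100 person-years).
#' @export
incidence_rate <- function(events, person_years, conf_level = 0.95) {
  if (person_years <= 0) stop("person_years must be > 0")
  if (events < 0) stop("events must be >= 0")
  a <- 1 - conf_level
  lo <- if (events == 0) 0 else stats::qchisq(a / 2, 2 * events) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * events + 2) / 2
  data.frame(events = events, person_years = person_years,
             rate = 100 * events / person_years,
             lower = 100 * lo / person_years, upper = 100 * hi / person_years)
}

#' Incidence rate ratio with log-normal interval
#'
#' Ratio of two incidence rates; the confidence interval uses the log-normal
#' approximation with `SE = sqrt(1/a + 1/b)` on the event counts.
#'
#' @param events_a,person_years_a Events and person-years in the numerator
#'   group.
#' @param events_b,person_years_b Events and person-years in the denominator
#'   group.
#' @param conf_level Confidence level (default 0.95).
#' @return Data.frame `irr`, `lower`, `upper`.
#' @export
incidence_rate_ratio <- function(events_a, person_years_a,
                                 events_b, person_years_b, conf_level = 0.95) {
  if (person_years_a <= 0 || person_years_b <= 0) stop("person-years must be > 0")
  if (events_a <= 0 || events_b <= 0) {
    stop("both groups need at least one event for the log-normal interval")
  }
  ratio <- (events_a / person_years_a) / (events_b / person_years_b)
  se <- sqrt(1 / events_a + 1 / events_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(irr = ratio, lower = ratio * exp(-z * se), upper = ratio * exp(z * se))
}
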