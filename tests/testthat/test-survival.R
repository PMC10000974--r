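test_that("endpoints impute progression at death when none was documented", {
  eps <- as_endpoints(
    data.frame(patient_id = c("A", "B", "C"), follow_up = c(10, 8, 6),
               death_observed = c(TRUE, TRUE, FALSE)),
    data.frame(patient_id = "A", time = 4))
  # B died without documented progression: imputed at the death time
  expect_equal(eps$progressions$time[eps$progressions$patient_id == "B"], 8)
  expect_true(eps$first$progression_observed[eps$first$patient_id == "B"])
  expect_equal(eps$first$ttp, c(4, 8, 6))
  expect_equal(eps$first$progression_observed, c(TRUE, TRUE, FALSE))
  expect_error(as_endpoints(data.frame(patient_id = "A", follow_up = 0,
                                       death_observed = FALSE)), "positive")
  expect_error(as_endpoints(
    data.frame(patient_id = "A", follow_up = 5, death_observed = FALSE),
    data.frame(patient_id = "A", time = 6)), "follow_up")
})

test_that("Kaplan-Meier product-limit matches hand computations", {
  # deaths at 1, 2, 3 with no censoring: S = 2/3, 1/3, 0; median 2
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$estimate, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(km$median$median, 2)
  # {1, 2+, 3}: risk set of 1 at t = 3, so S(1) = 2/3, S(3) = 0
  km2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  est <- km2$curve$estimate[km2$curve$n_event > 0]
  expect_equal(est, c(2/3, 0), tolerance = 1e-12)
  # single censored subject: S identically 1, median undefined
  km3 <- km_fit(5, 0)
  expect_equal(km3$curve$estimate, 1)
  expect_true(is.na(km3$median$median))
  # no censoring: complement of the empirical CDF, for arbitrary data
  set.seed(5)
  tt <- round(rexp(40, 0.2), 3)
  km4 <- km_fit(tt, rep(1, 40))
  ecdf_surv <- 1 - ecdf(tt)(km4$curve$time)
  expect_equal(km4$curve$estimate, ecdf_surv, tolerance = 1e-12)
})

test_that("Cox fit matches a grid-search maximizer of the Breslow likelihood", {
  d <- data.frame(time = c(1, 2.5, 3, 4.2, 5, 7), event = c(1, 1, 0, 1, 1, 1),
                  x = c(1, 0, 1, 1, 0, 0))
  fit <- cox_fit(d, "x")
  oracle <- grid_cox(d$time, d$event, d$x)
  expect_equal(fit$terms$coef, oracle, tolerance = 1e-4)
  expect_equal(fit$terms$hr, exp(fit$terms$coef))
  expect_equal(fit$nevents, 5)
})

test_that("Cox fit validates inputs and reports separation", {
  d <- data.frame(time = 1:6, event = rep(0, 6), x = rep(0:1, 3))
  expect_error(cox_fit(d, "x"), "no events")
  d$event <- 1
  d$z <- 1
  expect_error(cox_fit(d, "z"), "constant")
  # perfect separation: all events in one group, none in the other
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 0, 0, 0), x = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(sep, "x"), "separation|infinite")
})

test_that("counting-process rows on unchanging covariates equal the simple fit", {
  set.seed(8)
  n <- 60
  d <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.7),
                  x = rbinom(n, 1, 0.5))
  simple <- cox_fit(d, "x")
  d2 <- data.frame(start = 0, stop = d$time, event = d$event, x = d$x)
  cp <- cox_fit(d2, "x", start = "start", stop = "stop", event = "event")
  expect_equal(cp$terms$coef, simple$terms$coef, tolerance = 1e-10)
  expect_equal(cp$loglik, simple$loglik, tolerance = 1e-10)
})

test_that("LVCF counting-process construction splits at measurements and events", {
  eps <- as_endpoints(
    data.frame(patient_id = "A", follow_up = 5, death_observed = FALSE),
    data.frame(patient_id = "A", time = 5))
  meas <- data.frame(patient_id = "A", time = c(0, 3), ctc_count = c(2, 7))
  tab <- build_counting_process(eps, meas, mode = "single_event",
                                outcome = "progression")
  expect_equal(tab$start, c(0, 3))
  expect_equal(tab$stop, c(3, 5))
  expect_equal(tab$event, c(0L, 1L))
  expect_equal(tab$ctc_count, c(2, 7))     # carried forward from its own time

  # recurrent PWP total-time layout: strata 1, 2, 3 over (0,4], (4,9], (9,12]
  eps2 <- as_endpoints(
    data.frame(patient_id = "A", follow_up = 12, death_observed = FALSE),
    data.frame(patient_id = "A", time = c(4, 9)))
  tab2 <- build_counting_process(eps2,
    data.frame(patient_id = "A", time = 0, ctc_count = 3),
    mode = "recurrent_pwp")
  expect_equal(tab2$start, c(0, 4, 9))
  expect_equal(tab2$stop, c(4, 9, 12))
  expect_equal(tab2$event, c(1L, 1L, 0L))
  expect_equal(tab2$stratum, 1:3)
})

test_that("counting-process time is conserved and counts are truncated", {
  cfg <- cohort_config(n_patients = 50, seed = 13)
  coh <- generate_cohort(cfg)
  meas <- coh$visits[c("patient_id", "visit", "months", "ctc_count")]
  meas$time <- meas$months
  tab <- suppressMessages(suppressWarnings(
    build_counting_process(coh$endpoints, meas[c("patient_id", "time", "ctc_count")],
                           mode = "recurrent_pwp")))
  tot <- tapply(tab$stop - tab$start, tab$patient_id, sum)
  fu <- setNames(coh$endpoints$patients$follow_up,
                 coh$endpoints$patients$patient_id)
  expect_equal(as.vector(tot), unname(fu[names(tot)]), tolerance = 1e-9)
  expect_true(all(tab$ctc_count <= 40))               # truncation applied
  expect_true(all(tab$stop > tab$start))
  # a measurement after the end of follow-up is ignored with a warning
  eps <- as_endpoints(data.frame(patient_id = "A", follow_up = 5,
                                 death_observed = FALSE))
  late <- data.frame(patient_id = "A", time = c(0, 7), ctc_count = c(1, 9))
  expect_warning(build_counting_process(eps, late, mode = "single_event"),
                 "ignored")
})

test_that("PWP on single-event-per-patient data degenerates to the Cox fit", {
  set.seed(14)
  n <- 40
  fu <- runif(n, 2, 20)
  ev <- rbinom(n, 1, 0.6)
  pid <- sprintf("p%02d", 1:n)
  eps <- as_endpoints(
    data.frame(patient_id = pid, follow_up = fu, death_observed = FALSE),
    data.frame(patient_id = pid[ev == 1], time = fu[ev == 1]))
  meas <- data.frame(patient_id = pid, time = 0, x = rbinom(n, 1, 0.5))
  tab <- build_counting_process(eps, meas, mode = "recurrent_pwp")
  pw <- suppressWarnings(pwp_fit(tab, "x"))
  tab1 <- build_counting_process(eps, meas, mode = "single_event",
                                 outcome = "progression")
  single <- cox_fit(as.data.frame(tab1), "x", start = "start", stop = "stop",
                    event = "event", cluster = "patient_id")
  expect_equal(pw$terms$coef, single$terms$coef, tolerance = 1e-10)
  expect_equal(pw$terms$se, single$terms$se, tolerance = 1e-10)
  expect_equal(pw$variance, "robust_sandwich")
})

test_that("Nelson MCF reproduces hand-computed step functions", {
  # A: events at 1, 3, censored 5; B: event at 2, censored 4; both at risk
  ev <- data.frame(patient_id = c("A", "A", "B"), time = c(1, 3, 2))
  fu <- data.frame(patient_id = c("A", "B"), time = c(5, 4))
  mcf <- nelson_mcf(ev, fu)
  expect_equal(mcf$time, c(1, 2, 3))
  expect_equal(mcf$mcf, c(0.5, 1.0, 1.5), tolerance = 1e-12)
  # no events
  mcf0 <- nelson_mcf(data.frame(patient_id = character(), time = numeric()), fu)
  expect_equal(nrow(mcf0), 0)
  # one subject with events at 1, 2, 3: MCF(3) = 3
  mcf1 <- nelson_mcf(data.frame(patient_id = "A", time = 1:3),
                     data.frame(patient_id = "A", time = 3))
  expect_equal(mcf1$mcf, c(1, 2, 3))
})

test_that("pooled MCF with single events and no censoring is the ECDF count", {
  set.seed(15)
  n <- 30
  tt <- sort(round(runif(n, 1, 50), 3))
  fu <- max(tt)
  ev <- data.frame(patient_id = sprintf("p%02d", 1:n), time = tt)
  fudf <- data.frame(patient_id = sprintf("p%02d", 1:n), time = fu)
  mcf <- nelson_mcf(ev, fudf)
  expect_equal(mcf$mcf, seq_len(n) / n, tolerance = 1e-12)
})

test_that("MCF agrees with the survfit cumulative hazard on recurrent data", {
  set.seed(16)
  n <- 25
  fu <- runif(n, 5, 24)
  pid <- sprintf("p%02d", 1:n)
  evl <- lapply(1:n, function(i) {
    k <- rpois(1, 0.2 * fu[i]); if (k) sort(runif(k, 0, fu[i])) else numeric()
  })
  ev <- data.frame(patient_id = rep(pid, lengths(evl)), time = unlist(evl))
  mcf <- nelson_mcf(ev, data.frame(patient_id = pid, time = fu))
  rows <- do.call(rbind, lapply(1:n, function(i) {
    times <- sort(c(evl[[i]], fu[i]))
    data.frame(id = pid[i], start = c(0, head(times, -1)), stop = times,
               event = as.integer(times %in% evl[[i]]))
  }))
  sf <- survival::survfit(survival::Surv(start, stop, event) ~ 1, data = rows,
                          id = id)
  ch <- sf$cumhaz[sf$n.event > 0]
  expect_equal(mcf$mcf, ch, tolerance = 1e-10)
})

test_that("incidence rates use exact Poisson bounds; IRR uses log-normal SE", {
  r <- incidence_rate(10, 50)
  expect_equal(r$rate, 20)
  expect_equal(r$lower, 100 * qchisq(0.025, 20) / 2 / 50, tolerance = 1e-12)
  r0 <- incidence_rate(0, 10)
  expect_equal(r0$rate, 0)
  expect_equal(r0$lower, 0)
  expect_equal(r0$upper, 100 * qchisq(0.975, 2) / 2 / 10, tolerance = 1e-9)
  expect_equal(round(r0$upper, 2), 36.89)    # the 3.689 exact bound for 0 events
  rr <- incidence_rate_ratio(10, 50, 5, 50)
  expect_equal(rr$irr, 2)
  se <- sqrt(1/10 + 1/5)
  expect_equal(rr$lower, 2 * exp(-qnorm(0.975) * se), tolerance = 1e-12)
  expect_error(incidence_rate(3, 0), "person_years")
  expect_error(incidence_rate_ratio(0, 10, 5, 10), "at least one event")
})
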