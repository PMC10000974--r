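#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a 184-patient metastatic
#' breast cancer CTC cohort sampled at up to 9 visits at 3-month intervals
#' with healthy-donor (HD) calibration arms of 54 (RBC lysis) and 55 (no
#' lysis) samples.  The baseline CTC count model is a three-component
#' mixture chosen so that about 39% of baseline samples have 0 CTCs and
#' about 84% have fewer than 5: a structural-zero patient class, a
#' negative-binomial typical class, and a small high-burden class giving the
#' heavy upper tail (counts in the thousands).  Progression and death times
#' follow piecewise-constant hazards multiplied by the current CTC >= 5
#' state, triple-negative subtype, and the current FGFR1-high expression
#' state, with default log hazard ratios ln 2.251 / ln 4.894 (CTC >= 5 on
#' progression / death), ln 1.725 / ln 3.389 (TNBC) and ln 1.470 (FGFR1 on
#' progression).  EM polarity drifts mesenchymal in progressors and
#' epithelial in non-progressors.
#'
#' @param n_patients Number of patients (default 184).
#' @param n_hd_lysis,n_hd_nolysis HD calibration samples per processing arm
#'   (defaults 54 and 55).
#' @param n_visits Maximum number of visits (default 9).
#' @param visit_interval Months between visits (default 3).
#' @param followup_cap Administrative censoring time in months (default 25:
#'   the 2-year sampling window plus the 1-month visit-scheduling allowance,
#'   so the month-24 visit is observable).
#' @param subtype_probs Named probabilities of metastatic-site subtype
#'   (defaults: HR+HER2- 0.576, HR-HER2+ 0.054, HR+HER2+ 0.076, TNBC 0.201,
#'   unknown 0.092; normalised to sum to 1).
#' @param p_zero_class,p_high_class Probability of the structural-zero and
#'   high-burden patient classes (defaults 0.0807 and 0.05).
#' @param nb_mu,nb_size Negative-binomial mean and dispersion of the typical
#'   class baseline burden (defaults 1.937 and 0.9).
#' @param high_meanlog,high_sdlog Lognormal parameters of the high-burden
#'   class (burden = 5 + lognormal; defaults log(25) and 1.5).
#' @param count_decay Multiplicative per-visit decay of the latent burden
#'   under therapy (default 0.75).
#' @param base_progression_rate,base_death_rate Baseline hazards per month of
#'   the progression-event process and of its fatal sub-process (defaults
#'   0.045 and 0.010, chosen so the Kaplan-Meier median time to first
#'   progression is about 10 months and the median overall survival lies
#'   beyond the 2-year window).  Death is modelled as a fatal progression
#'   event, so `base_death_rate * exp(death log-HRs)` must not exceed
#'   `base_progression_rate * exp(progression log-HRs)` anywhere.
#' @param dropout_rate Exponential dropout hazard per month (default 0.04,
#'   giving roughly 4-5 samples per patient).
#' @param loghr_ctc_progression,loghr_ctc_death Log hazard ratios of the
#'   current CTC >= cutoff state.
#' @param loghr_tnbc_progression,loghr_tnbc_death Log hazard ratios of the
#'   triple-negative subtype.
#' @param loghr_fgfr1_progression Log hazard ratio of the current FGFR1-high
#'   expression state on progression.
#' @param ctc_cutoff CTC count cutoff used by the hazard model (default 5).
#' @param p_fgfr1_high Fraction of patients whose CTCs overexpress FGFR1
#'   (default 0.30).
#' @param fgfr1_boost Ct decrease (cycles) of FGFR1 in overexpressing
#'   patients (default 8).
#' @param em_baseline_sd SD of the baseline EM polarity state (default 0.3).
#' @param em_drift_progressor,em_drift_nonprogressor Per-visit drift of the
#'   EM polarity state (defaults +0.05 and -0.05).
#' @param signal_slope Ct decrease per unit log1p(CTC count) linking tumor
#'   burden to CTC-gene expression (default 2.5 cycles).
#' @param hd_ct Data.frame `gene`, `mean`, `sd`: HD background Ct per gene;
#'   defaults: CTC-related genes 37 (SD 1), housekeeping 20 (SD 0.5), PTPRC
#'   24 (SD 1), GYPA 30 (SD 1.5).  The same per-gene SD is used as Ct noise
#'   in patient samples.
#' @param arm_ct_offset Ct offset (cycles) added to samples processed
#'   without RBC lysis (default 0.5).
#' @param p_lysis Probability that a patient sample is processed with RBC
#'   lysis (default 0.5).
#' @param cluster_threshold,cluster_rate CTC clusters are Poisson with mean
#'   `cluster_rate * (count - cluster_threshold)` when the count exceeds the
#'   threshold, 0 otherwise (defaults 4 and 0.28, giving about 4%
#'   cluster-positive samples).
#' @param lines_gt1_prob Probability of more than one prior line of therapy
#'   (default 0.239).
#' @param seed Integer seed; mandatory for generation.
#' @return A list of class `ctc_config`.
#' @export
cohort_config <- function(n_patients = 184,
                          n_hd_lysis = 54, n_hd_nolysis = 55,
                          n_visits = 9, visit_interval = 3, followup_cap = 25,
                          subtype_probs = c(hr_pos_her2_neg = 0.576,
                                            hr_neg_her2_pos = 0.054,
                                            hr_pos_her2_pos = 0.076,
                                            tnbc = 0.201, unknown = 0.092),
                          p_zero_class = 0.0807, p_high_class = 0.05,
                          nb_mu = 1.937, nb_size = 0.9,
                          high_meanlog = log(25), high_sdlog = 1.5,
                          count_decay = 0.75,
                          base_progression_rate = 0.045,
                          base_death_rate = 0.010,
                          dropout_rate = 0.04,
                          loghr_ctc_progression = log(2.251),
                          loghr_ctc_death = log(4.894),
                          loghr_tnbc_progression = log(1.725),
                          loghr_tnbc_death = log(3.389),
                          loghr_fgfr1_progression = log(1.470),
                          ctc_cutoff = 5,
                          p_fgfr1_high = 0.30, fgfr1_boost = 8,
                          em_baseline_sd = 0.3,
                          em_drift_progressor = 0.05,
                          em_drift_nonprogressor = -0.05,
                          signal_slope = 2.5,
                          hd_ct = NULL, arm_ct_offset = 0.5, p_lysis = 0.5,
                          cluster_threshold = 4, cluster_rate = 0.28,
                          lines_gt1_prob = 0.239,
                          seed = NULL) {
  if (is.null(hd_ct)) hd_ct <- default_hd_background()
  cfg <- as.list(environment())
  probs <- c(cfg$p_zero_class, cfg$p_high_class, cfg$p_lysis, cfg$p_fgfr1_high,
             cfg$lines_gt1_prob, cfg$subtype_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_zero_class + cfg$p_high_class >= 1) {
    stop("infeasible count-model calibration: p_zero_class + p_high_class >= 1; ",
         "decrease one of them")
  }
  if (cfg$nb_size <= 0 || cfg$nb_mu <= 0) stop("NB dispersion and mean must be > 0")
  if (cfg$count_decay <= 0) stop("count_decay must be > 0")
  # progression events carry the death process as fatal marks: the documented
  # (non-fatal) rate lambda_p e^{bp x} - lambda_d e^{bd x} must be >= 0 at
  # every covariate combination
  for (ctc in 0:1) for (tn in 0:1) {
    hp <- cfg$base_progression_rate *
      exp(cfg$loghr_ctc_progression * ctc + cfg$loghr_tnbc_progression * tn)
    hd <- cfg$base_death_rate *
      exp(cfg$loghr_ctc_death * ctc + cfg$loghr_tnbc_death * tn)
    if (hp < hd) {
      stop("infeasible hazard calibration: the death hazard exceeds the ",
           "progression hazard at ctc_high = ", ctc, ", tnbc = ", tn,
           "; decrease base_death_rate or its log hazard ratios")
    }
  }
  cfg$subtype_probs <- cfg$subtype_probs / sum(cfg$subtype_probs)
  class(cfg) <- "ctc_config"
  cfg
}

#' Default healthy-donor Ct background per panel gene
#'
#' @param panel Gene panel.
#' @return Data.frame `gene`, `mean`, `sd` (Ct cycles).
#' @export
default_hd_background <- function(panel = ctc_gene_panel()) {
  mean_ct <- ifelse(panel$class == "housekeeping", 20,
             ifelse(panel$class == "wbc_control", 24,
             ifelse(panel$class == "rbc_control", 30, 37)))
  sd_ct <- ifelse(panel$class == "housekeeping", 0.5,
           ifelse(panel$class == "rbc_control", 1.5, 1))
  data.frame(gene = panel$symbol, mean = mean_ct, sd = sd_ct,
             stringsAsFactors = FALSE)
}

# HD sample Ct draws for one arm (no reseeding; part of the caller's stream)
.draw_hd_arm <- function(config, n, rbc_lysis, prefix) {
  hd <- config$hd_ct
  off <- if (rbc_lysis) 0 else config$arm_ct_offset
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  grid <- expand.grid(sample_id = ids, gene = hd$gene, stringsAsFactors = FALSE)
  grid <- merge(grid, hd, by = "gene")
  grid$ct <- pmin(40, pmax(0, stats::rnorm(nrow(grid), grid$mean + off, grid$sd)))
  data.frame(sample_id = grid$sample_id, patient_id = grid$sample_id,
             visit = NA_integer_, rbc_lysis = rbc_lysis,
             gene = grid$gene, ct = grid$ct, stringsAsFactors = FALSE)
}

#' Generate a healthy-donor calibration set
#'
#' HD Ct values per gene are normal around the configured background means
#' (truncated to `[0, 40]`), with the no-lysis arm shifted by the configured
#' arm offset.
#'
#' @param config A `ctc_config`; `config$seed` must be set.
#' @param n_lysis,n_nolysis Number of HD samples per arm (defaults from the
#'   config).
#' @return A `ctc_ct` table of HD samples covering both arms.
#' @export
generate_hd_set <- function(config, n_lysis = config$n_hd_lysis,
                            n_nolysis = config$n_hd_nolysis) {
  stopifnot(inherits(config, "ctc_config"))
  if (is.null(config$seed)) stop("config$seed must be set for reproducibility")
  set.seed(config$seed)
  df <- rbind(.draw_hd_arm(config, n_lysis, TRUE, "HDL"),
              .draw_hd_arm(config, n_nolysis, FALSE, "HDN"))
  as_ct_data(df)
}

#' Generate a synthetic longitudinal CTC cohort
#'
#' Jointly generates patients, visit-level CTC counts and clusters, the Ct
#' matrix, the HD calibration set and progression/death endpoints.  The
#' latent tumor burden drives counts (Poisson around a per-patient burden
#' decaying under therapy); gene Ct equals the HD background minus
#' `signal_slope * log1p(count)` weighted by EM polarity for the 8 EM genes;
#' event times are drawn from piecewise-constant hazards whose multipliers
#' are evaluated on the current CTC >= cutoff and FGFR1-high states
#' (last value carried forward between visits); censoring occurs at the
#' administrative cap or at dropout.  Covariate trajectories are generated
#' first, events second, and the EM drift is then assigned from the realised
#' progressor status, so the generating model is exactly the time-dependent
#' proportional-hazards model the fitting machinery assumes.
#'
#' @param config A `ctc_config` with a non-`NULL` seed.
#' @return A list of class `ctc_cohort`: `patients`, `visits`, `ct`
#'   (patient samples, `ctc_ct`), `hd` (`ctc_ct`), `endpoints`
#'   (`ctc_endpoints`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ctc_config"))
  if (is.null(config$seed)) stop("config$seed must be set for reproducibility")
  set.seed(config$seed)
  n <- config$n_patients
  nv <- config$n_visits
  vt <- config$visit_interval * (seq_len(nv) - 1)

  ## -- patients ------------------------------------------------------------
  pid <- sprintf("P%04d", seq_len(n))
  subtype <- sample(names(config$subtype_probs), n, TRUE, config$subtype_probs)
  tnbc <- subtype == "tnbc"
  fgfr1_flag <- stats::runif(n) < config$p_fgfr1_high
  lines_gt1 <- stats::runif(n) < config$lines_gt1_prob
  cls <- sample(c("zero", "high", "typical"), n, TRUE,
                c(config$p_zero_class, config$p_high_class,
                  1 - config$p_zero_class - config$p_high_class))
  burden <- numeric(n)
  burden[cls == "typical"] <- stats::rgamma(sum(cls == "typical"),
                                            shape = config$nb_size,
                                            scale = config$nb_mu / config$nb_size)
  burden[cls == "high"] <- 5 + stats::rlnorm(sum(cls == "high"),
                                             config$high_meanlog, config$high_sdlog)

  ## -- counts and covariate states at every scheduled visit -----------------
  counts <- matrix(0L, n, nv)
  for (v in seq_len(nv)) {
    counts[, v] <- stats::rpois(n, burden * config$count_decay^(v - 1))
  }
  high5 <- counts >= config$ctc_cutoff

  # FGFR1 expression state per scheduled sample (Ct drawn now, reused below)
  lysis <- matrix(stats::runif(n * nv) < config$p_lysis, n, nv)
  hd_bg <- config$hd_ct
  fg_mean <- hd_bg$mean[hd_bg$gene == "FGFR1"]
  fg_sd <- hd_bg$sd[hd_bg$gene == "FGFR1"]
  off <- ifelse(lysis, 0, config$arm_ct_offset)
  fg_ct <- pmin(40, pmax(0, stats::rnorm(n * nv,
             fg_mean + off - config$fgfr1_boost * fgfr1_flag, fg_sd)))
  fg_ct <- matrix(fg_ct, n, nv)
  # true positivity threshold of the generating HD background, per arm
  fg_thr <- (40 - (fg_mean + off)) + fg_sd
  fgfr1_high <- (40 - fg_ct) > fg_thr

  ## -- event times from piecewise-constant hazards --------------------------
  ## Progression is a marked point process with intensity
  ## base_p * exp(bp . x); an event is fatal (death) with a covariate-
  ## dependent mark probability so that the fatal sub-process has intensity
  ## base_d * exp(bd . x) exactly.  Death therefore always coincides with a
  ## progression event, matching the convention that a patient dying without
  ## documented progression progressed on the date of death; documented
  ## non-fatal progressions form the complementary thinned process.
  breaks <- c(vt[vt < config$followup_cap], config$followup_cap)
  nI <- length(breaks) - 1
  vidx <- findInterval(breaks[-length(breaks)], vt)  # visit whose state rules each interval
  h_death <- function(j) config$base_death_rate *
    exp(config$loghr_ctc_death * high5[, vidx[j]] + config$loghr_tnbc_death * tnbc)
  h_prog <- function(j) config$base_progression_rate *
    exp(config$loghr_ctc_progression * high5[, vidx[j]] +
        config$loghr_tnbc_progression * tnbc +
        config$loghr_fgfr1_progression * fgfr1_high[, vidx[j]])

  death <- rep(Inf, n); alive <- rep(TRUE, n)
  for (j in seq_len(nI)) {
    len <- breaks[j + 1] - breaks[j]
    e <- stats::rexp(n) / h_death(j)
    hit <- alive & e < len
    death[hit] <- breaks[j] + e[hit]
    alive <- alive & !hit
  }
  dropout <- stats::rexp(n, config$dropout_rate)
  censor <- pmin(config$followup_cap, dropout)
  follow_up <- pmin(death, censor)
  death_observed <- death <= censor

  prog_list <- vector("list", nI + 1)
  for (j in seq_len(nI)) {
    h <- pmax(0, h_prog(j) - h_death(j))     # documented non-fatal rate
    len <- pmax(0, pmin(breaks[j + 1], follow_up) - breaks[j])
    k <- stats::rpois(n, h * len)
    if (sum(k) > 0) {
      who <- rep(seq_len(n), k)
      prog_list[[j]] <- data.frame(patient_id = pid[who],
        time = breaks[j] + stats::runif(length(who)) * len[who])
    }
  }
  if (any(death_observed)) {                  # the fatal progression event
    prog_list[[nI + 1]] <- data.frame(patient_id = pid[death_observed],
                                      time = death[death_observed])
  }
  progressions <- do.call(rbind, prog_list[!vapply(prog_list, is.null, TRUE)])
  if (is.null(progressions)) {
    progressions <- data.frame(patient_id = character(), time = numeric())
  }
  progressor <- pid %in% progressions$patient_id

  ## -- EM polarity assigned from realised progressor status -----------------
  em0 <- pmin(1, pmax(-1, stats::rnorm(n, 0, config$em_baseline_sd)))
  drift <- ifelse(progressor, config$em_drift_progressor,
                  config$em_drift_nonprogressor)
  em_state <- matrix(pmin(1, pmax(-1, outer(em0, rep(1, nv)) +
                                       outer(drift, seq_len(nv) - 1))), n, nv)

  ## -- observed visits, clusters -------------------------------------------
  obs <- outer(follow_up, rep(1, nv)) > matrix(vt, n, nv, byrow = TRUE)
  iv <- which(obs, arr.ind = TRUE)
  visits <- data.frame(patient_id = pid[iv[, 1]], visit = iv[, 2],
                       months = vt[iv[, 2]],
                       ctc_count = counts[iv],
                       em_polarity = em_state[iv],
                       rbc_lysis = lysis[iv],
                       stringsAsFactors = FALSE)
  visits <- visits[order(visits$patient_id, visits$visit), ]
  rownames(visits) <- NULL
  cl_mean <- config$cluster_rate *
    pmax(0, visits$ctc_count - config$cluster_threshold)
  visits$cluster_count <- stats::rpois(nrow(visits), cl_mean)
  extra <- stats::rpois(nrow(visits), 0.5 * visits$cluster_count)
  visits$cells_in_clusters <- ifelse(visits$cluster_count > 0,
                                     2L * visits$cluster_count + extra, 0L)

  ## -- Ct matrix for patient samples ----------------------------------------
  panel <- ctc_gene_panel()
  sets <- em_gene_sets(panel)
  ctc_genes <- ctc_related_genes(panel)
  ns <- nrow(visits)
  long <- visits[rep(seq_len(ns), each = nrow(panel)),
                 c("patient_id", "visit", "rbc_lysis", "ctc_count", "em_polarity")]
  long$gene <- rep(panel$symbol, ns)
  long$sample_id <- sprintf("%s_V%d", long$patient_id, long$visit)
  long <- merge(long, hd_bg, by = "gene", sort = FALSE)
  w <- ifelse(long$gene %in% sets$mes, 1 + long$em_polarity,
       ifelse(long$gene %in% sets$epi, 1 - long$em_polarity,
       ifelse(long$gene %in% ctc_genes, 1, 0)))
  w[long$gene == "FGFR1"] <- 0          # FGFR1 signal is flag-driven, set below
  base_ct <- long$mean + ifelse(long$rbc_lysis, 0, config$arm_ct_offset)
  sig <- config$signal_slope * log1p(long$ctc_count) * w
  long$ct <- pmin(40, pmax(0, stats::rnorm(nrow(long), base_ct - sig, long$sd)))
  is_fg <- long$gene == "FGFR1"
  fg_key <- match(paste(long$patient_id[is_fg], long$visit[is_fg]),
                  paste(pid[iv[, 1]], iv[, 2]))
  long$ct[is_fg] <- fg_ct[iv][fg_key]
  ct <- as_ct_data(long[c("sample_id", "patient_id", "visit", "rbc_lysis",
                          "gene", "ct")])

  ## -- assemble --------------------------------------------------------------
  patients <- data.frame(patient_id = pid, subtype = subtype, tnbc = tnbc,
                         fgfr1_flag = fgfr1_flag, lines_gt1 = lines_gt1,
                         latent_class = cls, latent_burden = burden,
                         follow_up = follow_up, death_observed = death_observed,
                         progressor = progressor, stringsAsFactors = FALSE)
  endpoints <- as_endpoints(patients[c("patient_id", "follow_up", "death_observed")],
                            progressions)
  hd <- rbind(.draw_hd_arm(config, config$n_hd_lysis, TRUE, "HDL"),
              .draw_hd_arm(config, config$n_hd_nolysis, FALSE, "HDN"))
  structure(list(patients = patients, visits = visits, ct = ct,
                 hd = as_ct_data(hd), endpoints = endpoints, config = config),
            class = "ctc_cohort")
}

#' Implied marginal baseline count probabilities of a configuration
#'
#' Reports the probabilities of 0 CTCs and of fewer than `cutoff` CTCs at
#' baseline implied by the count-model parameters (by large-sample
#' evaluation), for checking a configuration against calibration targets.
#'
#' @param config A `ctc_config`.
#' @param cutoff Count cutoff (default 5).
#' @param n Monte-Carlo size (default 2e5).
#' @return Named numeric vector `p0`, `p_below`.
#' @export
count_model_probs <- function(config, cutoff = 5, n = 2e5) {
  stopifnot(inherits(config, "ctc_config"))
  cls <- sample(c("zero", "high", "typical"), n, TRUE,
                c(config$p_zero_class, config$p_high_class,
                  1 - config$p_zero_class - config$p_high_class))
  burden <- numeric(n)
  burden[cls == "typical"] <- stats::rgamma(sum(cls == "typical"),
    shape = config$nb_size, scale = config$nb_mu / config$nb_size)
  burden[cls == "high"] <- 5 + stats::rlnorm(sum(cls == "high"),
    config$high_meanlog, config$high_sdlog)
  x <- stats::rpois(n, burden)
  c(p0 = mean(x == 0), p_below = mean(x < cutoff))
}
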