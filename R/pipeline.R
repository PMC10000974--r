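#' Configuration of a full analysis run
#'
#' Either paths to the three input CSVs (Ct long table, counts table,
#' clinical table) or a synthetic-cohort configuration must be supplied.
#'
#' @param ct_path,counts_path,clinical_path Input CSV paths (see the module
#'   readers for the expected columns), or `NULL` to use `synth`.
#' @param synth A `ctc_config` used to generate the cohort when no input
#'   paths are given.
#' @param cutoff CTC count cutoff (default 5).
#' @param positive_gene_cutoff Positive-gene count cutoff (default 4).
#' @param truncation_cap Truncation cap for the continuous count covariate
#'   (default 40).
#' @param sweep_visit Visit used for the cutoff sweep (default 2).
#' @param output_dir Output directory (created if missing).
#' @param seed Integer seed for any run-level randomness.
#' @return A list of class `ctc_runconfig`.
#' @export
run_config <- function(ct_path = NULL, counts_path = NULL, clinical_path = NULL,
                       synth = NULL, cutoff = 5, positive_gene_cutoff = 4,
                       truncation_cap = 40, sweep_visit = 2,
                       output_dir = tempfile("ctcdx_run_"), seed = 1) {
  stopifnot(cutoff >= 1, positive_gene_cutoff >= 1)
  have_paths <- !is.null(ct_path) && !is.null(counts_path) && !is.null(clinical_path)
  if (!have_paths && is.null(synth)) {
    stop("supply either all three input paths or a synthetic `ctc_config`")
  }
  if (have_paths) {
    for (p in c(ct_path, counts_path, clinical_path)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }
  structure(as.list(environment()), class = "ctc_runconfig")
}

# write a data.frame as CSV with full precision, returning its manifest row
.emit <- function(df, name, dir) {
  path <- file.path(dir, name)
  utils::write.csv(format(df, digits = 8, trim = TRUE), path, row.names = FALSE,
                   quote = FALSE)
  data.frame(file = name, md5 = unname(tools::md5sum(path)), rows = nrow(df))
}

.coxfit_summary <- function(fit) {
  if (is.null(fit)) return(NULL)
  c(fit["terms"], fit[c("n", "nevents", "loglik", "variance", "ties")])
}

#' Run the full calibrate-score-fit-report pipeline
#'
#' Orchestrates the analysis end to end: HD threshold calibration, per-sample
#' scoring, per-visit comparisons, the cutoff sweep, Kaplan-Meier fits,
#' time-dependent Cox fits for death, the PWP recurrent-progression fit, the
#' Nelson mean-cumulative-function by baseline CTC group, and incidence
#' rates.  All outputs are written as CSV/JSON into the configured output
#' directory together with a run manifest (file hashes, seed, package
#' version).  Deterministic given inputs and seed.
#'
#' @param rc A `ctc_runconfig`.
#' @return Invisibly, the result bundle (a named list) that was serialized.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "ctc_runconfig"))
  dir.create(rc$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(rc$seed)

  if (!is.null(rc$synth)) {
    cohort <- generate_cohort(rc$synth)
    ct <- cohort$ct; hd <- cohort$hd
    visits <- cohort$visits
    endpoints <- cohort$endpoints
    patients <- cohort$patients
  } else {
    ct_all <- read_ct_csv(rc$ct_path)
    is_hd <- is.na(ct_all$visit)
    split_ct <- function(sel) {
      out <- ct_all[sel, ]
      class(out) <- c("ctc_ct", "data.frame")
      attr(out, "ct_max") <- attr(ct_all, "ct_max")
      qc <- ct_qc(ct_all)
      attr(out, "qc") <- qc[qc$sample_id %in% out$sample_id, ]
      out
    }
    hd <- split_ct(is_hd); ct <- split_ct(!is_hd)
    visits <- utils::read.csv(rc$counts_path, stringsAsFactors = FALSE)
    clinical <- utils::read.csv(rc$clinical_path, stringsAsFactors = FALSE)
    clinical$death_observed <- as.logical(clinical$death_observed)
    progressions <- clinical[!is.na(clinical$progression_time),
                             c("patient_id", "progression_time")]
    names(progressions)[2] <- "time"
    endpoints <- as_endpoints(clinical[c("patient_id", "follow_up",
                                         "death_observed")], progressions)
    patients <- clinical
  }

  thresholds <- calibrate_thresholds(hd)
  scores <- score_samples(ct, thresholds,
                          positive_gene_cutoff = rc$positive_gene_cutoff)
  progressor <- data.frame(patient_id = endpoints$first$patient_id,
                           progressor = endpoints$first$progression_observed)

  ## longitudinal measurements for the time-dependent models
  meas <- merge(visits[c("patient_id", "visit", "months", "ctc_count")],
                scores[c("patient_id", "visit", "positive_count", "gene_pos",
                         "fgfr1_high", "em_score")],
                by = c("patient_id", "visit"), all.x = TRUE)
  meas$ctc_high <- meas$ctc_count >= rc$cutoff
  meas$gene_pos[is.na(meas$gene_pos)] <- FALSE
  meas$fgfr1_high[is.na(meas$fgfr1_high)] <- FALSE
  meas <- meas[order(meas$patient_id, meas$visit), ]
  meas$time <- meas$months
  tnbc <- patients[c("patient_id", "tnbc")]
  meas <- merge(meas, tnbc, by = "patient_id")

  cp_cols <- c("patient_id", "time", "ctc_count", "ctc_high", "gene_pos",
               "fgfr1_high", "tnbc")
  cp_rec <- build_counting_process(endpoints, meas[cp_cols],
                                   mode = "recurrent_pwp",
                                   cap = rc$truncation_cap)
  cp_death <- build_counting_process(endpoints, meas[cp_cols],
                                     mode = "single_event", outcome = "death",
                                     cap = rc$truncation_cap)

  pfs_fit <- tryCatch(suppressWarnings(
    pwp_fit(cp_rec, c("ctc_high", "tnbc", "fgfr1_high"))),
    error = function(e) NULL)
  os_fit <- tryCatch(cox_fit(as.data.frame(cp_death), c("ctc_high", "tnbc"),
                             start = "start", stop = "stop", event = "event",
                             cluster = "patient_id"),
                     error = function(e) NULL)

  ## baseline stratification, MCF, incidence rates
  base <- visits[visits$visit == 1, c("patient_id", "ctc_count")]
  base$group <- as.character(dichotomize(base$ctc_count, rc$cutoff))
  fu <- endpoints$patients[c("patient_id", "follow_up")]
  names(fu)[2] <- "time"
  mcf <- nelson_mcf(endpoints$progressions, fu,
                    group = base[c("patient_id", "group")])
  py <- merge(fu, base[c("patient_id", "group")], by = "patient_id")
  rate_rows <- lapply(split(py, py$group), function(d) {
    ev <- sum(endpoints$progressions$patient_id %in% d$patient_id)
    cbind(group = d$group[1], incidence_rate(ev, sum(d$time) / 12))
  })
  rates <- do.call(rbind, rate_rows)
  irr <- if (all(c("high", "low") %in% rates$group) &&
             all(rates$events[match(c("high", "low"), rates$group)] > 0)) {
    hi <- rates[rates$group == "high", ]; lo <- rates[rates$group == "low", ]
    incidence_rate_ratio(hi$events, hi$person_years, lo$events, lo$person_years)
  } else NULL

  sweep <- cutoff_sweep(visits, endpoints, visit = rc$sweep_visit)
  km_pfs <- km_fit(endpoints$first$ttp, endpoints$first$progression_observed,
                   group = base$group[match(endpoints$first$patient_id,
                                            base$patient_id)])
  comparisons <- per_visit_rank_sum(
    merge(visits[c("patient_id", "visit", "ctc_count")], progressor,
          by = "patient_id"), "ctc_count", "progressor")
  emt <- em_trajectory(scores, progressor)
  cluster_em <- cluster_em_comparison(
    merge(scores[c("patient_id", "visit", "em_score")],
          visits[c("patient_id", "visit", "cluster_count")],
          by = c("patient_id", "visit")), progressor)

  bundle <- list(thresholds = thresholds, scores = scores, sweep = sweep,
                 pfs_fit = pfs_fit, os_fit = os_fit, mcf = mcf,
                 rates = rates, irr = irr, km_pfs = km_pfs,
                 comparisons = comparisons, em_trajectory = emt,
                 cluster_em = cluster_em)

  manifest <- rbind(
    .emit(as.data.frame(thresholds), "thresholds.csv", rc$output_dir),
    .emit(scores, "scores.csv", rc$output_dir),
    .emit(as.data.frame(sweep), "cutoff_sweep.csv", rc$output_dir),
    .emit(as.data.frame(mcf), "mcf.csv", rc$output_dir),
    .emit(rates, "incidence_rates.csv", rc$output_dir),
    .emit(km_pfs$curve, "km_pfs.csv", rc$output_dir),
    if (!is.null(comparisons)) .emit(comparisons, "per_visit_counts.csv", rc$output_dir),
    .emit(emt$per_visit, "em_trajectory.csv", rc$output_dir))
  fits <- list(pfs = .coxfit_summary(pfs_fit), os = .coxfit_summary(os_fit),
               irr = irr)
  jsonlite::write_json(fits, file.path(rc$output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  run_info <- list(package = "ctcdx",
                   version = as.character(utils::packageVersion("ctcdx")),
                   seed = rc$seed, cutoff = rc$cutoff,
                   positive_gene_cutoff = rc$positive_gene_cutoff,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   files = manifest)
  jsonlite::write_json(run_info, file.path(rc$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(bundle)
}
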