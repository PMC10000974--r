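#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration p-value when both groups are at most `exact_below_n` and
#' there are no ties; otherwise a normal approximation with tie and
#' continuity corrections.
#'
#' @param values_a,values_b Numeric vectors, both nonempty.
#' @param exact_below_n Use the exact distribution when both group sizes are
#'   at most this (default 25) and no ties are present.
#' @return List with `statistic` (rank-sum W of the first group), `p`,
#'   `exact` (logical), `n_a`, `n_b`.
#' @export
rank_sum_test <- function(values_a, values_b, exact_below_n = 25) {
  values_a <- values_a[!is.na(values_a)]; values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && length(values_a) <= exact_below_n && length(values_b) <= exact_below_n
  ht <- stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value, exact = exact,
       n_a = length(values_a), n_b = length(values_b))
}

#' Wilcoxon signed-rank test for paired change from baseline
#'
#' Differences `followup - baseline` paired by patient; zero differences are
#' dropped (Wilcoxon convention).  Exact for up to 20 nonzero pairs with
#' untied absolute differences, normal approximation otherwise.  With no
#' nonzero pairs the p-value is undefined and returned as `NA`.
#'
#' @param baseline_values,followup_values Paired numeric vectors of equal
#'   length.
#' @param exact_below_n Exact enumeration limit (default 20).
#' @return List with `statistic` (V), `p`, `n_nonzero`, `exact`.
#' @export
signed_rank_change <- function(baseline_values, followup_values,
                               exact_below_n = 20) {
  stopifnot(length(baseline_values) == length(followup_values))
  keep <- !is.na(baseline_values) & !is.na(followup_values)
  d <- followup_values[keep] - baseline_values[keep]
  d <- d[d != 0]
  if (!length(d)) {
    return(list(statistic = NA_real_, p = NA_real_, n_nonzero = 0L, exact = NA))
  }
  exact <- length(d) <= exact_below_n && !anyDuplicated(abs(d))
  ht <- stats::wilcox.test(d, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n_nonzero = length(d), exact = exact)
}

#' Bonferroni-Holm step-down correction
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order), monotone in the ranks of the raw
#'   p-values and never above 1.
#' @export
holm_correction <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Per-visit rank-sum comparisons of a measure between two groups
#'
#' Runs [rank_sum_test()] at each visit comparing a per-sample measure
#' between patient groups (e.g. progressors vs non-progressors), and attaches
#' Holm-adjusted p-values across visits.
#'
#' @param data Data.frame with columns `visit`, a value column and a logical
#'   group column.
#' @param value_col Name of the value column.
#' @param group_col Name of the logical group column (`TRUE` = first group).
#' @return Data.frame: `visit`, `n_true`, `n_false`, `median_true`,
#'   `median_false`, `statistic`, `p`, `p_holm`.  Visits with an empty group
#'   are skipped.
#' @export
per_visit_rank_sum <- function(data, value_col, group_col) {
  rows <- lapply(sort(unique(data$visit)), function(v) {
    d <- data[data$visit == v & !is.na(data[[value_col]]), ]
    a <- d[[value_col]][d[[group_col]]]; b <- d[[value_col]][!d[[group_col]]]
    if (!length(a) || !length(b)) return(NULL)
    tt <- rank_sum_test(a, b)
    data.frame(visit = v, n_true = length(a), n_false = length(b),
               median_true = stats::median(a), median_false = stats::median(b),
               statistic = tt$statistic, p = tt$p)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_holm <- holm_correction(out$p)
  out
}

#' EM-score trajectories by progression status
#'
#' Per-visit group medians of the EM score for progressors vs non-progressors
#' with a Welch (unequal-variance) two-sample t-test at each visit, plus the
#' within-patient change of the EM score from baseline.  Samples with an
#' undefined EM score are excluded; a visit with fewer than 2 defined scores
#' in either group is reported without a test.
#'
#' @param scores Data.frame with `patient_id`, `visit`, `em_score` (e.g. from
#'   [score_samples()]).
#' @param progressors Data.frame with `patient_id`, `progressor` (logical
#'   patient-level label: experienced progression at some point on protocol).
#' @return List with `per_visit` (`visit`, group sizes and medians, `p`) and
#'   `change` (`patient_id`, `visit`, `em_change` from the patient's baseline
#'   score).
#' @export
em_trajectory <- function(scores, progressors) {
  d <- merge(scores[c("patient_id", "visit", "em_score")], progressors,
             by = "patient_id")
  d <- d[!is.na(d$em_score), ]
  rows <- lapply(sort(unique(d$visit)), function(v) {
    dv <- d[d$visit == v, ]
    a <- dv$em_score[dv$progressor]; b <- dv$em_score[!dv$progressor]
    p <- if (length(a) >= 2 && length(b) >= 2) {
      tryCatch(stats::t.test(a, b)$p.value,  # Welch by default
               error = function(e) NA_real_) # e.g. zero variance in both groups
    } else NA_real_
    data.frame(visit = v, n_prog = length(a), n_nonprog = length(b),
               median_prog = if (length(a)) stats::median(a) else NA_real_,
               median_nonprog = if (length(b)) stats::median(b) else NA_real_,
               p = p)
  })
  per_visit <- do.call(rbind, rows)
  base <- d[d$visit == min(d$visit), c("patient_id", "em_score")]
  names(base)[2] <- "em_baseline"
  ch <- merge(d, base, by = "patient_id")
  ch$em_change <- ch$em_score - ch$em_baseline
  list(per_visit = per_visit,
       change = ch[order(ch$patient_id, ch$visit),
                   c("patient_id", "visit", "em_change")])
}

#' EM score in samples with vs without CTC clusters
#'
#' Within each progression stratum, compares EM scores of samples with
#' detected CTC clusters (`cluster_count > 0`) against samples without, by
#' rank-sum test.  Empty strata are skipped.
#'
#' @param data Data.frame with `patient_id`, `em_score`, `cluster_count`.
#' @param progressors Data.frame with `patient_id`, `progressor` (logical).
#' @return Data.frame: `progressor`, `n_cluster`, `n_no_cluster`,
#'   `median_cluster`, `median_no_cluster`, `statistic`, `p`.
#' @export
cluster_em_comparison <- function(data, progressors) {
  d <- merge(data, progressors, by = "patient_id")
  d <- d[!is.na(d$em_score), ]
  rows <- lapply(c(TRUE, FALSE), function(pg) {
    dd <- d[d$progressor == pg, ]
    a <- dd$em_score[dd$cluster_count > 0]; b <- dd$em_score[dd$cluster_count == 0]
    if (!length(a) || !length(b)) return(NULL)
    tt <- rank_sum_test(a, b)
    data.frame(progressor = pg, n_cluster = length(a), n_no_cluster = length(b),
               median_cluster = stats::median(a),
               median_no_cluster = stats::median(b),
               statistic = tt$statistic, p = tt$p)
  })
  do.call(rbind, rows)
}
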