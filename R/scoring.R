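#' Calibrate per-gene positivity thresholds from healthy-donor samples
#'
#' For every gene and processing arm (with/without red-blood-cell lysis) the
#' positivity threshold is the mean plus one sample standard deviation
#' (divisor n - 1) of the healthy-donor (HD) expression levels in that arm.
#' A patient sample's gene is later called positive when its expression is
#' strictly above this threshold.
#'
#' @param hd_ct A `ctc_ct` table of HD samples covering both processing arms.
#' @param panel Gene panel (default [ctc_gene_panel()]).
#' @return A data.frame of class `ctc_thresholds` with columns `gene`,
#'   `rbc_lysis`, `hd_mean`, `hd_sd`, `threshold`, `n_hd`.
#' @export
calibrate_thresholds <- function(hd_ct, panel = ctc_gene_panel()) {
  stopifnot(inherits(hd_ct, "ctc_ct"))
  arms <- sort(unique(hd_ct$rbc_lysis))
  if (length(arms) < 2) {
    stop("HD samples must cover both processing arms (with and without RBC lysis)")
  }
  for (arm in arms) {
    n <- length(unique(hd_ct$sample_id[hd_ct$rbc_lysis == arm]))
    if (n < 2) {
      stop(sprintf("calibration needs >= 2 HD samples in the %s arm (found %d)",
                   if (arm) "RBC-lysis" else "no-lysis", n))
    }
  }
  agg <- stats::aggregate(expression ~ gene + rbc_lysis, data = hd_ct,
                          FUN = function(x) c(m = mean(x), s = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(gene = agg$gene, rbc_lysis = agg$rbc_lysis,
                    hd_mean = agg$expression[, "m"],
                    hd_sd = agg$expression[, "s"],
                    n_hd = as.integer(agg$expression[, "n"]),
                    stringsAsFactors = FALSE)
  out$threshold <- out$hd_mean + out$hd_sd
  out <- out[order(out$gene, out$rbc_lysis),
             c("gene", "rbc_lysis", "hd_mean", "hd_sd", "threshold", "n_hd")]
  rownames(out) <- NULL
  class(out) <- c("ctc_thresholds", "data.frame")
  out
}

# join a ct table with its arm-matched thresholds; errors on unknown genes/arms
.join_thresholds <- function(ct, thresholds) {
  stopifnot(inherits(ct, "ctc_ct"), inherits(thresholds, "ctc_thresholds"))
  missing_arm <- setdiff(unique(ct$rbc_lysis), unique(thresholds$rbc_lysis))
  if (length(missing_arm)) {
    stop("no thresholds calibrated for arm rbc_lysis = ",
         paste(missing_arm, collapse = ", "))
  }
  m <- merge(as.data.frame(ct), as.data.frame(thresholds),
             by = c("gene", "rbc_lysis"), all.x = TRUE)
  if (anyNA(m$threshold)) {
    stop("genes without calibrated thresholds: ",
         paste(unique(m$gene[is.na(m$threshold)]), collapse = ", "))
  }
  m[order(m$sample_id, m$gene), ]
}

#' Call positive genes against healthy-donor thresholds
#'
#' A gene is positive when its expression is strictly higher than the
#' threshold of its processing arm; expression exactly at the threshold is
#' negative.  `positive_count` counts CTC-related genes only (controls and
#' housekeeping genes are never counted).
#'
#' @param ct A `ctc_ct` table of patient samples.
#' @param thresholds A `ctc_thresholds` table from [calibrate_thresholds()].
#' @param panel Gene panel (default [ctc_gene_panel()]).
#' @return A list with `calls` (long data.frame: `sample_id`, `gene`,
#'   `expression`, `threshold`, `positive`) and `counts` (per-sample
#'   data.frame with `sample_id`, `positive_count`).
#' @export
call_positive_genes <- function(ct, thresholds, panel = ctc_gene_panel()) {
  m <- .join_thresholds(ct, thresholds)
  m$positive <- m$expression > m$threshold
  ctc_genes <- ctc_related_genes(panel)
  cc <- m[m$gene %in% ctc_genes, ]
  counts <- stats::aggregate(positive ~ sample_id, data = cc, FUN = sum)
  names(counts)[2] <- "positive_count"
  counts$positive_count <- as.integer(counts$positive_count)
  list(calls = m[c("sample_id", "patient_id", "visit", "rbc_lysis",
                   "gene", "expression", "threshold", "positive")],
       counts = counts)
}

#' Classify a single gene as high or low versus healthy donors
#'
#' High means expression strictly above mean + 1 SD of the arm-matched HD
#' level; used e.g. for the FGFR1 covariate and for calling HER2+ CTCs from
#' \emph{ERBB2} expression.
#'
#' @param ct A `ctc_ct` table.
#' @param thresholds A `ctc_thresholds` table.
#' @param gene Single gene symbol.
#' @return Data.frame with `sample_id`, `patient_id`, `visit`, `expression`,
#'   `threshold` and `group` (factor `low`/`high`).
#' @export
classify_gene_group <- function(ct, thresholds, gene) {
  gene <- toupper(gene)
  sub <- ct[ct$gene == gene, , drop = FALSE]
  if (!nrow(sub)) stop("gene not present in the Ct table: ", gene)
  class(sub) <- class(ct)
  attr(sub, "qc") <- attr(ct, "qc")
  m <- .join_thresholds(sub, thresholds)
  m$group <- factor(ifelse(m$expression > m$threshold, "high", "low"),
                    levels = c("low", "high"))
  m[c("sample_id", "patient_id", "visit", "expression", "threshold", "group")]
}

#' Summed expression over a gene subset
#'
#' @param ct A `ctc_ct` table.
#' @param subset `"all_ctc"` (17 CTC-related genes), `"epithelial"` or
#'   `"mesenchymal"` (see [expression_subset_genes()]).
#' @param panel Gene panel.
#' @return Data.frame with `sample_id` and `total_expression` (expression
#'   units, i.e. summed `40 - Ct`).
#' @export
total_expression <- function(ct, subset = c("all_ctc", "epithelial", "mesenchymal"),
                             panel = ctc_gene_panel()) {
  stopifnot(inherits(ct, "ctc_ct"))
  genes <- expression_subset_genes(match.arg(subset), panel)
  sub <- ct[ct$gene %in% genes, ]
  out <- stats::aggregate(expression ~ sample_id, data = sub, FUN = sum)
  names(out)[2] <- "total_expression"
  out
}

#' Epithelial-mesenchymal (EM) score
#'
#' For the 4 mesenchymal/stem EM genes (\emph{ALDH1A1}, \emph{CDH2},
#' \emph{FN1}, \emph{ZEB2}) and the 4 epithelial EM genes (\emph{CDH1},
#' \emph{EPCAM}, \emph{KRT7}, \emph{KRT18}),
#' \deqn{EM = \frac{\sum_{mes}(40 - Ct) - \sum_{epi}(40 - Ct)}
#'                 {\sum_{all\,8}(40 - Ct)}}
#' so a sample in which only mesenchymal/stem genes are detected scores +1 and
#' one in which only epithelial genes are detected scores -1.  When no EM gene
#' is detected the denominator is 0 and the score is undefined (`NA`); such
#' samples are excluded from downstream EM analyses rather than coerced to 0.
#'
#' @param ct A `ctc_ct` table.
#' @param panel Gene panel.
#' @return Data.frame with `sample_id`, `patient_id`, `visit`, `epi_sum`,
#'   `mes_sum`, `all_sum` (expression units) and `em_score` in `[-1, 1]` or
#'   `NA`.
#' @export
em_score <- function(ct, panel = ctc_gene_panel()) {
  stopifnot(inherits(ct, "ctc_ct"))
  sets <- em_gene_sets(panel)
  em <- ct[ct$gene %in% c(sets$epi, sets$mes), ]
  n_per <- table(em$sample_id)
  if (any(n_per != 8)) {
    stop("samples without Ct for all 8 EM genes: ",
         paste(names(n_per)[n_per != 8], collapse = ", "))
  }
  em$side <- ifelse(em$gene %in% sets$mes, "mes", "epi")
  agg <- stats::aggregate(expression ~ sample_id + side, data = em, FUN = sum)
  wide <- stats::reshape(agg, direction = "wide", idvar = "sample_id",
                         timevar = "side")
  names(wide) <- sub("^expression\\.", "", names(wide))
  meta <- unique(ct[c("sample_id", "patient_id", "visit")])
  out <- merge(meta, wide, by = "sample_id")
  out$all_sum <- out$epi + out$mes
  out$em_score <- ifelse(out$all_sum > 0, (out$mes - out$epi) / out$all_sum, NA_real_)
  names(out)[names(out) == "epi"] <- "epi_sum"
  names(out)[names(out) == "mes"] <- "mes_sum"
  out[order(out$sample_id),
      c("sample_id", "patient_id", "visit", "epi_sum", "mes_sum", "all_sum", "em_score")]
}

#' Healthy-donor Z-scores of gene expression
#'
#' `Z = (expression - hd_mean) / hd_sd` with the HD statistics of the sample's
#' processing arm, so expression exactly at the positivity threshold maps to
#' `Z = 1`.  Genes whose HD standard deviation is 0 get `NA` with a QC note.
#'
#' @param ct A `ctc_ct` table.
#' @param thresholds A `ctc_thresholds` table.
#' @return Long data.frame `sample_id`, `gene`, `z`, plus attribute
#'   `qc_zero_sd`: genes (per arm) whose Z-scores are undefined.
#' @export
hd_zscore <- function(ct, thresholds) {
  m <- .join_thresholds(ct, thresholds)
  m$z <- ifelse(m$hd_sd > 0, (m$expression - m$hd_mean) / m$hd_sd, NA_real_)
  zero <- unique(m[m$hd_sd == 0, c("gene", "rbc_lysis")])
  out <- m[c("sample_id", "patient_id", "visit", "gene", "z")]
  attr(out, "qc_zero_sd") <- zero
  out
}

#' Concordance between CTC-based and tissue-based HER2 status
#'
#' Cross-tabulates per-patient HER2 status called from CTC \emph{ERBB2}
#' expression against the clinical status of the metastatic tissue.  Patients
#' missing either status are excluded and reported.
#'
#' @param ctc_status Named logical vector (names = patient ids): HER2+ CTCs.
#' @param tissue_status Named logical vector: clinical HER2+ tissue.
#' @return List with `table` (2 x 2 contingency table), `patients`
#'   (per-patient labels `concordant+`, `concordant-`, `discordant`) and
#'   `n_excluded`.
#' @export
her2_concordance <- function(ctc_status, tissue_status) {
  ids <- union(names(ctc_status), names(tissue_status))
  ctc <- ctc_status[ids]; tis <- tissue_status[ids]
  keep <- !is.na(ctc) & !is.na(tis) & ids %in% names(ctc_status) &
    ids %in% names(tissue_status)
  n_excluded <- sum(!keep)
  ctc <- ctc[keep]; tis <- tis[keep]; ids <- ids[keep]
  tab <- table(factor(ctc, levels = c(FALSE, TRUE), labels = c("CTC-", "CTC+")),
               factor(tis, levels = c(FALSE, TRUE), labels = c("tissue-", "tissue+")))
  lab <- ifelse(ctc == tis, ifelse(ctc, "concordant+", "concordant-"), "discordant")
  patients <- data.frame(patient_id = ids, ctc_her2 = ctc, tissue_her2 = tis,
                         label = lab, stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, patients = patients, n_excluded = n_excluded)
}

#' Master per-sample score table
#'
#' Combines positive-gene counts, summed expression, EM score and the HER2 and
#' FGFR1 expression groups into one table.  Samples flagged for exclusion by
#' the QC log (too many missing wells) are dropped.
#'
#' @param ct A `ctc_ct` table of patient samples.
#' @param thresholds A `ctc_thresholds` table.
#' @param positive_gene_cutoff Samples with at least this many positive
#'   CTC-related genes are flagged `gene_pos` (default 4).
#' @param panel Gene panel.
#' @return Data.frame, one row per sample: ids, `positive_count`, `gene_pos`,
#'   `total_all`, `total_epithelial`, `total_mesenchymal`, `em_score`,
#'   `her2_ctc`, `fgfr1_high`.
#' @export
score_samples <- function(ct, thresholds, positive_gene_cutoff = 4,
                          panel = ctc_gene_panel()) {
  stopifnot(positive_gene_cutoff >= 1)
  qc <- ct_qc(ct)
  ct_max <- attr(ct, "ct_max")
  drop <- qc$sample_id[qc$excluded]
  if (length(drop)) {
    ct <- ct[!ct$sample_id %in% drop, ]
    class(ct) <- c("ctc_ct", "data.frame")
    attr(ct, "qc") <- qc
    attr(ct, "ct_max") <- ct_max
  }
  pos <- call_positive_genes(ct, thresholds, panel)
  out <- unique(ct[c("sample_id", "patient_id", "visit", "rbc_lysis")])
  out <- merge(out, pos$counts, by = "sample_id")
  for (sub in c("all_ctc", "epithelial", "mesenchymal")) {
    te <- total_expression(ct, sub, panel)
    names(te)[2] <- paste0("total_", sub("all_ctc", "all", sub))
    out <- merge(out, te, by = "sample_id")
  }
  out <- merge(out, em_score(ct, panel)[c("sample_id", "em_score")], by = "sample_id")
  her2 <- classify_gene_group(ct, thresholds, "ERBB2")
  out <- merge(out, data.frame(sample_id = her2$sample_id,
                               her2_ctc = her2$group == "high"), by = "sample_id")
  fg <- classify_gene_group(ct, thresholds, "FGFR1")
  out <- merge(out, data.frame(sample_id = fg$sample_id,
                               fgfr1_high = fg$group == "high"), by = "sample_id")
  out$gene_pos <- out$positive_count >= positive_gene_cutoff
  out[order(out$patient_id, out$visit), ]
}
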