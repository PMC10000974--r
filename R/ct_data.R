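#' Convert a qPCR cycle threshold to an expression level
#'
#' Expression is measured on the inverted Ct scale, `ct_max - ct`, so that an
#' undetected well (Ct at the assay limit) has expression 0 and lower Ct means
#' higher expression.
#'
#' @param ct Numeric vector of cycle-threshold values in `[0, ct_max]`.
#' @param ct_max Assay limit in cycles (default 40); undetected wells are
#'   encoded as `ct = ct_max`.
#' @return Numeric vector of expression levels in `[0, ct_max]`.
#' @examples
#' expression_from_ct(c(40, 25, 0))  # 0, 15, 40
#' @export
expression_from_ct <- function(ct, ct_max = 40) {
  if (!is.numeric(ct)) stop("`ct` must be numeric")
  bad <- !is.na(ct) & (ct < 0 | ct > ct_max)
  if (any(bad)) {
    stop(sprintf("Ct values outside [0, %g]: %s", ct_max,
                 paste(utils::head(ct[bad], 5), collapse = ", ")))
  }
  ct_max - ct
}

#' Assemble a validated long Ct table
#'
#' Takes long-format qPCR data (one row per sample and gene) and returns a
#' validated table with expression levels attached.  Gene symbols are
#' normalised to upper case; wells missing for a panel gene are filled in as
#' undetected (`ct = ct_max`) and recorded in the QC log; samples missing more
#' than `max_missing_frac` of panel wells are flagged `excluded` in the QC log
#' and dropped from downstream score computations by [score_samples()].
#'
#' @param df Data.frame with columns `sample_id`, `patient_id`, `visit`,
#'   `rbc_lysis` (logical: processed with red-blood-cell lysis), `gene`, `ct`.
#' @param ct_max Assay limit in cycles (default 40).
#' @param panel Gene panel (default [ctc_gene_panel()]); rows for genes not in
#'   the panel are rejected.
#' @param max_missing_frac Samples missing more than this fraction of panel
#'   wells are flagged for exclusion (default 0.25).
#' @return A data.frame of class `ctc_ct` with columns `sample_id`,
#'   `patient_id`, `visit`, `rbc_lysis`, `gene`, `ct`, `expression`, and
#'   attributes `ct_max` and `qc` (per-sample QC log).
#' @export
as_ct_data <- function(df, ct_max = 40, panel = ctc_gene_panel(),
                       max_missing_frac = 0.25) {
  need <- c("sample_id", "patient_id", "visit", "rbc_lysis", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$gene <- toupper(as.character(df$gene))
  unknown <- setdiff(unique(df$gene), panel$symbol)
  if (length(unknown)) {
    stop("genes not in the panel: ", paste(unknown, collapse = ", "))
  }
  if (!is.logical(df$rbc_lysis)) stop("`rbc_lysis` must be logical")
  if (anyNA(df$rbc_lysis)) stop("`rbc_lysis` must not contain NA")
  df$ct[is.na(df$ct)] <- ct_max                     # empty well = undetected
  invisible(expression_from_ct(df$ct, ct_max))      # range validation
  key <- paste(df$sample_id, df$gene)
  if (anyDuplicated(key)) stop("duplicate (sample_id, gene) rows")

  # fill wells absent for panel genes as undetected, keeping a QC log
  samples <- unique(df[c("sample_id", "patient_id", "visit", "rbc_lysis")])
  if (anyDuplicated(samples$sample_id)) {
    stop("inconsistent sample metadata across rows of the same sample_id")
  }
  full <- merge(samples, data.frame(gene = panel$symbol), by = NULL)
  out <- merge(full, df, by = c("sample_id", "patient_id", "visit",
                                "rbc_lysis", "gene"), all.x = TRUE)
  filled <- is.na(out$ct)
  out$ct[filled] <- ct_max
  out$expression <- expression_from_ct(out$ct, ct_max)
  out <- out[order(out$sample_id, out$gene), ]
  rownames(out) <- NULL

  n_missing <- tapply(filled, out$sample_id, sum)
  qc <- data.frame(sample_id = names(n_missing),
                   n_missing = as.integer(n_missing),
                   excluded = as.vector(n_missing) > max_missing_frac * nrow(panel),
                   stringsAsFactors = FALSE)
  attr(out, "ct_max") <- ct_max
  attr(out, "qc") <- qc
  class(out) <- c("ctc_ct", "data.frame")
  out
}

#' Read a Ct CSV file (long or wide layout)
#'
#' Long layout: columns `sample_id`, `patient_id`, `visit`, `rbc_lysis`,
#' `gene`, `ct`.  Wide layout: one row per sample with the same metadata
#' columns plus one column per gene symbol.
#'
#' @param path Path to a CSV file.
#' @param format `"long"` or `"wide"`.
#' @param ... Passed on to [as_ct_data()].
#' @return A `ctc_ct` table (see [as_ct_data()]).
#' @export
read_ct_csv <- function(path, format = c("long", "wide"), ...) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (identical(format, "wide")) {
    meta <- c("sample_id", "patient_id", "visit", "rbc_lysis")
    genes <- setdiff(names(df), meta)
    df <- stats::reshape(df, direction = "long", varying = genes,
                         v.names = "ct", times = genes, timevar = "gene",
                         idvar = "sample_id")
    rownames(df) <- NULL
  }
  df$rbc_lysis <- as.logical(df$rbc_lysis)
  as_ct_data(df, ...)
}

#' Per-sample QC log of a Ct table
#'
#' @param ct A `ctc_ct` table.
#' @return Data.frame with `sample_id`, `n_missing`, `excluded`.
#' @export
ct_qc <- function(ct) {
  stopifnot(inherits(ct, "ctc_ct"))
  attr(ct, "qc")
}
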