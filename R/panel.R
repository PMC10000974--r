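#' The default 22-gene CTC qRT-PCR panel
#'
#' Returns the gene panel used throughout the package: 17 CTC-related genes
#' (epithelial, EMT, cancer-stem-cell and signalling classes), one white-blood-
#' cell control (\emph{PTPRC}/CD45), one nucleated-red-blood-cell control
#' (\emph{GYPA}) and three housekeeping genes.  The `em_epi`/`em_mes` flags mark
#' the 4 + 4 genes entering the epithelial-mesenchymal (EM) score: \emph{CDH1},
#' \emph{EPCAM}, \emph{KRT7}, \emph{KRT18} as epithelial and \emph{ALDH1A1},
#' \emph{CDH2}, \emph{FN1}, \emph{ZEB2} as mesenchymal/stem.  Genes of
#' ambiguous polarity (e.g. \emph{FGFR1}) carry neither flag.
#'
#' @return A data.frame with columns `symbol`, `class` (one of `epithelial`,
#'   `emt`, `csc`, `signaling`, `wbc_control`, `rbc_control`, `housekeeping`),
#'   `em_epi` and `em_mes` (logical).
#' @examples
#' panel <- ctc_gene_panel()
#' table(panel$class)
#' @export
ctc_gene_panel <- function() {
  panel <- data.frame(
    symbol = c("CDH1", "EGFR", "EPCAM", "KRT7", "KRT18", "MUC1",
               "AXL", "CDH2", "FN1", "SNAI2", "ZEB2",
               "ALDH1A1",
               "BCL2", "CD274", "ERBB2", "FGFR1", "MET",
               "PTPRC", "GYPA",
               "B2M", "GAPDH", "HPRT1"),
    class = c(rep("epithelial", 6), rep("emt", 5), "csc",
              rep("signaling", 5), "wbc_control", "rbc_control",
              rep("housekeeping", 3)),
    stringsAsFactors = FALSE
  )
  panel$em_epi <- panel$symbol %in% c("CDH1", "EPCAM", "KRT7", "KRT18")
  panel$em_mes <- panel$symbol %in% c("ALDH1A1", "CDH2", "FN1", "ZEB2")
  panel
}

#' CTC-related genes of the panel
#'
#' The 17 genes of classes epithelial, EMT, CSC and signalling.  Control and
#' housekeeping genes are excluded from all patient-facing scores.
#'
#' @param panel A gene panel as returned by [ctc_gene_panel()].
#' @return Character vector of gene symbols.
#' @export
ctc_related_genes <- function(panel = ctc_gene_panel()) {
  panel$symbol[panel$class %in% c("epithelial", "emt", "csc", "signaling")]
}

#' Gene subsets used for summed expression
#'
#' The epithelial subset is \{CDH1, EPCAM, KRT18, KRT7, MUC1\} and the
#' mesenchymal/CSC subset is \{ALDH1A1, CDH2, FN1, ZEB2\}; `all_ctc` is the
#' full 17-gene CTC-related panel.
#'
#' @param subset One of `"all_ctc"`, `"epithelial"`, `"mesenchymal"`.
#' @param panel A gene panel as returned by [ctc_gene_panel()].
#' @return Character vector of gene symbols.
#' @export
expression_subset_genes <- function(subset = c("all_ctc", "epithelial", "mesenchymal"),
                                    panel = ctc_gene_panel()) {
  subset <- match.arg(subset)
  switch(subset,
    all_ctc      = ctc_related_genes(panel),
    epithelial   = c("CDH1", "EPCAM", "KRT18", "KRT7", "MUC1"),
    mesenchymal  = c("ALDH1A1", "CDH2", "FN1", "ZEB2"))
}

#' EM-score gene sets
#'
#' @param panel A gene panel as returned by [ctc_gene_panel()].
#' @return A list with components `epi` and `mes`, each a character vector of
#'   4 gene symbols.
#' @export
em_gene_sets <- function(panel = ctc_gene_panel()) {
  list(epi = panel$symbol[panel$em_epi], mes = panel$symbol[panel$em_mes])
}
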