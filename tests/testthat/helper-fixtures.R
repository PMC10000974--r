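# Build a one-sample long Ct table from a named vector of Ct values; genes
# not mentioned are filled in as undetected by as_ct_data().
toy_ct <- function(ct, sample_id = "S1", patient_id = "P1", visit = 1,
                   rbc_lysis = TRUE, ...) {
  as_ct_data(data.frame(sample_id = sample_id, patient_id = patient_id,
                        visit = visit, rbc_lysis = rbc_lysis,
                        gene = names(ct), ct = unname(ct),
                        stringsAsFactors = FALSE), ...)
}

# Same, from expression levels (expression = 40 - Ct).
toy_expr <- function(expr, ...) toy_ct(40 - expr, ...)

# HD table with per-sample expression values for one gene in both arms; all
# other panel genes are undetected in every sample.
toy_hd <- function(gene, expr_lysis, expr_nolysis = expr_lysis) {
  mk <- function(vals, lys, pre) {
    do.call(rbind, lapply(seq_along(vals), function(i) {
      data.frame(sample_id = sprintf("%s%02d", pre, i),
                 patient_id = sprintf("%s%02d", pre, i), visit = NA_integer_,
                 rbc_lysis = lys, gene = gene, ct = 40 - vals[i],
                 stringsAsFactors = FALSE)
    }))
  }
  as_ct_data(rbind(mk(expr_lysis, TRUE, "HL"), mk(expr_nolysis, FALSE, "HN")))
}

# Thresholds table fixed at given values for every panel gene and both arms.
flat_thresholds <- function(hd_mean = 0, hd_sd = 0, n_hd = 10,
                            panel = ctc_gene_panel()) {
  out <- expand.grid(gene = panel$symbol, rbc_lysis = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  out$hd_mean <- hd_mean
  out$hd_sd <- hd_sd
  out$threshold <- hd_mean + hd_sd
  out$n_hd <- n_hd
  class(out) <- c("ctc_thresholds", "data.frame")
  out
}

# The 4+4 EM gene sets, for readability in tests.
EM_MES <- c("ALDH1A1", "CDH2", "FN1", "ZEB2")
EM_EPI <- c("CDH1", "EPCAM", "KRT7", "KRT18")

# Hand-written Breslow log partial likelihood (independent oracle for Cox
# fits; no ties assumed handled by the data used in tests).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Two-stage grid-search maximizer of the Breslow partial likelihood.
grid_cox <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 1e-3)
  ll <- vapply(grid, breslow_loglik, 0, time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  llf <- vapply(fine, breslow_loglik, 0, time = time, event = event, x = x)
  fine[which.max(llf)]
}
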