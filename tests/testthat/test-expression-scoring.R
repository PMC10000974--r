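test_that("expression is the inverted Ct scale with validation", {
  expect_equal(expression_from_ct(40), 0)    # undetected
  expect_equal(expression_from_ct(25), 15)
  expect_equal(expression_from_ct(0), 40)    # saturation
  expect_error(expression_from_ct(41), "outside")
  expect_error(expression_from_ct(-1), "outside")
})

test_that("Ct ingestion fills missing wells, flags heavy missingness, normalises symbols", {
  ct <- toy_ct(c(cdh1 = 25, EPCAM = 30))
  expect_equal(nrow(ct), 22)                         # all panel genes present
  expect_equal(ct$ct[ct$gene == "CDH1"], 25)         # case-insensitive input
  expect_equal(ct$expression[ct$gene == "MET"], 0)   # filled as undetected
  qc <- ct_qc(ct)
  expect_equal(qc$n_missing, 20L)
  expect_true(qc$excluded)                           # > 25% of wells missing
  full <- toy_ct(setNames(rep(30, 22), ctc_gene_panel()$symbol))
  expect_false(ct_qc(full)$excluded)
  expect_error(toy_ct(c(NOTAGENE = 20)), "not in the panel")
  expect_error(as_ct_data(data.frame(sample_id = "S", patient_id = "P",
                                     visit = 1, rbc_lysis = TRUE,
                                     gene = c("CDH1", "CDH1"), ct = c(1, 2))),
               "duplicate")
})

test_that("HD thresholds are mean + 1 sample SD per gene and arm", {
  thr <- calibrate_thresholds(toy_hd("CDH1", c(1, 2, 3)))
  row <- thr[thr$gene == "CDH1" & thr$rbc_lysis, ]
  expect_equal(row$hd_mean, 2)
  expect_equal(row$hd_sd, 1)                 # sample SD of consecutive integers
  expect_equal(row$threshold, 3)
  expect_equal(row$n_hd, 3L)

  # degenerate: all HD expression 0 means any detection is positive
  thr0 <- calibrate_thresholds(toy_hd("CDH1", c(0, 0, 0)))
  expect_equal(thr0$threshold[thr0$gene == "CDH1" & thr0$rbc_lysis], 0)

  # direct mean + SD hand computation: {0, 0, 6} -> 2 + sqrt(12)
  thr2 <- calibrate_thresholds(toy_hd("CDH1", c(0, 0, 6)))
  expect_equal(thr2$threshold[thr2$gene == "CDH1" & thr2$rbc_lysis],
               2 + sqrt(12), tolerance = 1e-12)

  # both arms required, and at least 2 samples per arm
  one_arm <- toy_ct(c(CDH1 = 30), sample_id = c("A"), patient_id = "A")
  expect_error(calibrate_thresholds(one_arm), "both processing arms")
})

test_that("positivity is strictly above threshold and counts CTC genes only", {
  thr <- flat_thresholds(hd_mean = 2, hd_sd = 1)   # threshold 3 everywhere
  s <- toy_expr(c(CDH1 = 3, EPCAM = 3.0001, PTPRC = 40, GAPDH = 40))
  res <- call_positive_genes(s, thr)
  calls <- res$calls
  expect_false(calls$positive[calls$gene == "CDH1"])       # tie is negative
  expect_true(calls$positive[calls$gene == "EPCAM"])
  expect_equal(res$counts$positive_count, 1L)               # controls excluded

  # all expression zero -> zero positives; all 17 CTC genes high -> 17
  expect_equal(call_positive_genes(toy_expr(c(CDH1 = 0)), thr)$counts$positive_count, 0L)
  hi <- setNames(rep(40, 17), ctc_related_genes())
  expect_equal(call_positive_genes(toy_expr(hi), thr)$counts$positive_count, 17L)

  # arm without calibrated thresholds is an error
  thr_lysis_only <- flat_thresholds()
  thr_lysis_only <- thr_lysis_only[thr_lysis_only$rbc_lysis, ]
  class(thr_lysis_only) <- c("ctc_thresholds", "data.frame")
  expect_error(call_positive_genes(toy_expr(c(CDH1 = 5), rbc_lysis = FALSE),
                                   thr_lysis_only), "arm")
})

test_that("positive count is monotone when any expression increases", {
  thr <- flat_thresholds(hd_mean = 3, hd_sd = 2)
  set.seed(11)
  genes <- ctc_related_genes()
  for (i in 1:20) {
    expr <- setNames(runif(17, 0, 10), genes)
    n0 <- call_positive_genes(toy_expr(expr), thr)$counts$positive_count
    g <- sample(genes, 1)
    expr[g] <- expr[g] + runif(1, 0, 10)
    n1 <- call_positive_genes(toy_expr(pmin(expr, 40)), thr)$counts$positive_count
    expect_gte(n1, n0)
  }
})

test_that("single-gene high/low classification matches the HER2-CTC rule", {
  thr <- flat_thresholds(hd_mean = 2, hd_sd = 1)
  s <- toy_expr(c(ERBB2 = 5, FGFR1 = 0))
  expect_equal(as.character(classify_gene_group(s, thr, "ERBB2")$group), "high")
  at_thr <- toy_expr(c(ERBB2 = 3))
  expect_equal(as.character(classify_gene_group(at_thr, thr, "ERBB2")$group), "low")
  thr0 <- flat_thresholds(0, 0)
  expect_equal(as.character(classify_gene_group(toy_expr(c(FGFR1 = 0)), thr0,
                                                "FGFR1")$group), "low")
})

test_that("summed expression over subsets is plain arithmetic on 40 - Ct", {
  all40 <- toy_ct(setNames(rep(40, 22), ctc_gene_panel()$symbol))
  expect_equal(total_expression(all40, "all_ctc")$total_expression, 0)
  two <- toy_ct(c(CDH1 = 30, EPCAM = 35))
  expect_equal(total_expression(two, "all_ctc")$total_expression, 15)
  sat <- toy_ct(setNames(rep(0, 17), ctc_related_genes()))
  expect_equal(total_expression(sat, "all_ctc")$total_expression, 17 * 40)
  expect_equal(total_expression(two, "epithelial")$total_expression, 15)
  expect_equal(total_expression(two, "mesenchymal")$total_expression, 0)
})

test_that("EM score hits the +1/-1 boundaries and handles the 0/0 case", {
  mes_only <- toy_ct(c(setNames(c(30, 32, 35, 28), EM_MES),
                       setNames(rep(40, 4), EM_EPI)))
  expect_equal(em_score(mes_only)$em_score, 1)
  epi_only <- toy_ct(c(setNames(rep(40, 4), EM_MES),
                       setNames(c(25, 30, 33, 39), EM_EPI)))
  expect_equal(em_score(epi_only)$em_score, -1)
  # mes_sum 30, epi_sum 10 -> (30 - 10) / 40 = 0.5
  mixed <- toy_expr(c(setNames(c(10, 10, 10, 0), EM_MES),
                      setNames(c(10, 0, 0, 0), EM_EPI)))
  res <- em_score(mixed)
  expect_equal(res$mes_sum, 30); expect_equal(res$epi_sum, 10)
  expect_equal(res$all_sum, 40); expect_equal(res$em_score, 0.5)
  # all 8 EM genes undetected: undefined, not coerced to 0
  none <- toy_ct(setNames(rep(40, 8), c(EM_MES, EM_EPI)))
  expect_true(is.na(em_score(none)$em_score))
})

test_that("EM score is antisymmetric, scale-invariant and bounded", {
  set.seed(21)
  for (i in 1:25) {
    e <- runif(4, 0, 12); m <- runif(4, 0, 12)
    s <- em_score(toy_expr(c(setNames(m, EM_MES), setNames(e, EM_EPI))))$em_score
    swapped <- em_score(toy_expr(c(setNames(e, EM_MES), setNames(m, EM_EPI))))$em_score
    expect_equal(swapped, -s, tolerance = 1e-12)
    cc <- runif(1, 0.1, 3)
    scaled <- em_score(toy_expr(c(setNames(cc * m, EM_MES),
                                  setNames(cc * e, EM_EPI))))$em_score
    # absolute tolerance: scores near 0 amplify relative rounding error
    expect_lt(abs(scaled - s), 1e-8)
    expect_true(abs(s) <= 1)
  }
})

test_that("HD Z-scores put the threshold at exactly Z = 1", {
  thr <- flat_thresholds(hd_mean = 5, hd_sd = 2)
  s <- toy_expr(c(CDH1 = 5, EPCAM = 7))
  z <- hd_zscore(s, thr)
  expect_equal(z$z[z$gene == "CDH1"], 0)
  expect_equal(z$z[z$gene == "EPCAM"], 1)     # threshold level maps to Z = 1
  thr0 <- flat_thresholds(hd_mean = 5, hd_sd = 0)
  z0 <- hd_zscore(s, thr0)
  expect_true(all(is.na(z0$z)))
  expect_gt(nrow(attr(z0, "qc_zero_sd")), 0)
})

test_that("HER2 CTC-vs-tissue concordance cross-tabulates and logs exclusions", {
  ctc <- c(A = TRUE, B = TRUE, C = FALSE, D = TRUE)
  tissue <- c(A = TRUE, B = FALSE, C = FALSE)
  res <- her2_concordance(ctc, tissue)
  expect_equal(res$n_excluded, 1)                       # D has no tissue status
  expect_equal(unname(res$table["CTC+", "tissue+"]), 1)
  expect_equal(unname(res$table["CTC+", "tissue-"]), 1)  # the discordant pattern
  expect_equal(res$patients$label[res$patients$patient_id == "B"], "discordant")
  expect_equal(res$patients$label[res$patients$patient_id == "C"], "concordant-")
  empty <- her2_concordance(logical(), logical())
  expect_true(all(empty$table == 0))
})

test_that("score_samples assembles one row per sample and drops QC failures", {
  thr <- flat_thresholds(hd_mean = 2, hd_sd = 1)
  good <- setNames(rep(30, 22), ctc_gene_panel()$symbol)
  df <- rbind(
    data.frame(sample_id = "S1", patient_id = "P1", visit = 1, rbc_lysis = TRUE,
               gene = names(good), ct = unname(good)),
    data.frame(sample_id = "S2", patient_id = "P2", visit = 1, rbc_lysis = TRUE,
               gene = "CDH1", ct = 20))            # 21 wells missing: excluded
  sc <- score_samples(as_ct_data(df), thr, positive_gene_cutoff = 4)
  expect_equal(sc$sample_id, "S1")
  expect_equal(sc$positive_count, 17L)
  expect_true(sc$gene_pos && sc$her2_ctc && sc$fgfr1_high)
  expect_equal(sc$total_all, 17 * 10)
})
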