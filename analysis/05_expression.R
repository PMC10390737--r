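#!/usr/bin/env Rscript
# Delta-delta-Ct relative expression and gated group statistics on a
# planted three-arm Ct table (reference gene RPL27).

library(slicequant)

ct <- simulate_ct_table(
  genes = c("MAP2", "BDNF", "GFAP", "CD11b"),
  n_ctrl = 6, n_tbi = 6,
  true_log2fc = c(MAP2 = -1.5, BDNF = -1.5, GFAP = 1, CD11b = 1),
  ct_noise_sd = 0.3, seed = 42,
  treated2 = list(label = "TBI+MSC-sec", n = 6,
                  log2fc = c(MAP2 = -0.7, BDNF = -0.7, GFAP = 0.5,
                             CD11b = 0.5)))
fc <- delta_delta_ct(ct, ctrl_group = "CTRL")
write.csv(fc, "results/expression_log2fc.csv", row.names = FALSE)

for (g in unique(fc$gene)) {
  sub <- fc[fc$gene == g, ]
  means <- tapply(sub$log2fc, sub$group, mean)
  res <- compare_groups(sub$log2fc, sub$group)
  message(sprintf(
    "%-6s mean log2FC CTRL/TBI/TBI+MSC-sec = %5.2f / %5.2f / %5.2f | %s (%s) p = %.4g",
    g, means["CTRL"], means["TBI"], means["TBI+MSC-sec"],
    res$test, res$branch, res$p_value))
  if (!is.null(res$posthoc)) {
    ph <- res$posthoc
    for (i in seq_len(nrow(ph)))
      message(sprintf("        %-28s adj. p = %.4g", ph$contrast[i],
                      ph$p_adjusted[i]))
  }
}

# biomarker-style table through the same gated statistics
bm <- simulate_biomarker_table(c("NfL", "Tau", "UCH-L1"), n_per_group = 6,
                               fold_change = c(NfL = 3, Tau = 2.5,
                                               `UCH-L1` = 2), seed = 43)
for (a in unique(bm$analyte)) {
  sub <- bm[bm$analyte == a, ]
  res <- compare_groups(log(sub$concentration_pg_ml), sub$group)
  message(sprintf("%-6s (biomarker) %s p = %.4g", a, res$test, res$p_value))
}
message("planted MAP2/BDNF downregulation should be recovered near -1.5 ",
        "with the treated arm near -0.7")
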