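make_records <- function(ct_by_sample, groups, gene = "G", ref_ct = 18) {
  ids <- sprintf("S%02d", seq_along(ct_by_sample))
  rbind(
    data.frame(sample_id = ids, group = groups, gene = gene,
               ct = ct_by_sample, is_reference = FALSE),
    data.frame(sample_id = ids, group = groups, gene = "RPL27",
               ct = ref_ct, is_reference = TRUE))
}

test_that("delta-delta-Ct recovers hand-computed fold changes", {
  # control mean dCt = 7; a sample at the control mean has log2FC 0
  rec <- make_records(c(25, 25, 25, 25), c("CTRL", "CTRL", "TBI", "TBI"))
  fc <- delta_delta_ct(rec)
  expect_true(all(fc$log2fc == 0))
  # one cycle above the control mean (reference unchanged): 2-fold down
  rec2 <- make_records(c(25, 25, 26, 26), c("CTRL", "CTRL", "TBI", "TBI"))
  fc2 <- delta_delta_ct(rec2)
  expect_equal(fc2$log2fc[fc2$group == "TBI"], c(-1, -1))
  expect_equal(fc2$fold_change[fc2$group == "TBI"], c(0.5, 0.5))
  # control-group mean log2FC is 0 by construction
  rec3 <- make_records(c(24.2, 25.9, 25.1, 27), rep(c("CTRL", "TBI"), each = 2))
  expect_equal(mean(delta_delta_ct(rec3)$log2fc[1:2]), 0)
})

test_that("delta-delta-Ct is invariant to per-sample global Ct shifts", {
  rec <- make_records(c(25, 24.5, 26.5, 27), rep(c("CTRL", "TBI"), each = 2))
  fc0 <- delta_delta_ct(rec)
  shifted <- rec
  bump <- shifted$sample_id == "S03"   # all of S03's genes, reference included
  shifted$ct[bump] <- shifted$ct[bump] + 3.7
  expect_equal(delta_delta_ct(shifted)$log2fc, fc0$log2fc)
})

test_that("delta-delta-Ct reports missing references by sample", {
  rec <- make_records(c(25, 25, 26, 26), rep(c("CTRL", "TBI"), each = 2))
  broken <- rec[!(rec$sample_id == "S03" & rec$is_reference), ]
  expect_error(delta_delta_ct(broken), "S03")
  expect_error(delta_delta_ct(rec, ctrl_group = "SHAM"), "control group")
})

test_that("the normality gate picks branches as designed", {
  # normal draws pass the gate in at least 90% of seeds
  parametric <- 0
  for (s in 1:100) {
    set.seed(s)
    v <- rnorm(20)
    g <- rep(c("a", "b"), each = 10)
    if (choose_test(v, g)$branch == "parametric") parametric <- parametric + 1
  }
  expect_gte(parametric, 90)
  # a two-point distribution fails Shapiro-Wilk
  v2 <- c(rep(c(0, 1), 5), rnorm(10))
  g2 <- rep(c("a", "b"), each = 10)
  expect_equal(choose_test(v2, g2)$branch, "nonparametric")
  # order invariance
  set.seed(42)
  v3 <- rnorm(24); g3 <- rep(letters[1:3], each = 8)
  perm <- sample(24)
  expect_equal(choose_test(v3, g3)$branch,
               choose_test(v3[perm], g3[perm])$branch)
  expect_error(choose_test(rnorm(4), c("a", "a", "b", "b")),
               "insufficient")
})

test_that("one-way ANOVA and Tukey match the studentized-range oracle", {
  set.seed(5)
  df <- data.frame(y = c(rnorm(6, 10), rnorm(6, 11.2), rnorm(6, 10.4)),
                   g = rep(c("c1", "c2", "c3"), each = 6))
  got <- omnibus_posthoc(df, "y", "g", posthoc = "tukey")
  oracle <- brute_oneway_tukey(df$y, df$g)
  expect_equal(got$anova$statistic, oracle$f, tolerance = 1e-6)
  expect_equal(got$anova$p_value, oracle$p, tolerance = 1e-6)
  expect_equal(got$posthoc$p_adjusted, oracle$tukey$p_adjusted,
               tolerance = 1e-6)
  # identical groups: no between-group variance at all
  df0 <- data.frame(y = rep(c(1, 2, 3, 4), 2), g = rep(c("a", "b"), each = 4))
  got0 <- omnibus_posthoc(df0, "y", "g", posthoc = "tukey")
  expect_lt(got0$anova$statistic, 1e-12)
  expect_gt(got0$anova$p_value, 0.999)
})

test_that("two-way ANOVA uses type-II sums of squares", {
  set.seed(8)
  df <- expand.grid(region = c("lesion", "perilesion", "periphery"),
                    treatment = c("CTRL", "TBI"), rep = 1:4)
  df$y <- rnorm(nrow(df)) + (df$treatment == "TBI") * 1.5
  df <- df[-c(1, 9), ]  # unbalance the design
  got <- omnibus_posthoc(df, "y", "treatment", "region", posthoc = "sidak")
  # independent route: type-II F for treatment from nested model comparison
  full <- lm(y ~ treatment + region, df)
  red <- lm(y ~ region, df)
  cmp <- anova(red, full)
  resid_full <- lm(y ~ treatment * region, df)
  f_typeII <- (cmp$`Sum of Sq`[2] / cmp$Df[2]) /
    (sum(resid(resid_full)^2) / resid_full$df.residual)
  expect_equal(got$anova$statistic[got$anova$term == "treatment"],
               f_typeII, tolerance = 1e-6)
  expect_equal(got$design, "two-way")
  expect_true(all(c("treatment", "region", "treatment:region") %in%
                  got$anova$term))
})

test_that("post-hoc adjusted p-values never undercut unadjusted ones", {
  set.seed(13)
  df <- data.frame(y = rnorm(24), g = rep(letters[1:4], each = 6))
  for (ph in c("tukey", "sidak")) {
    got <- omnibus_posthoc(df, "y", "g", posthoc = ph)
    expect_true(all(got$posthoc$p_adjusted >= got$posthoc$p_unadjusted -
                    1e-12))
  }
})

test_that("gated comparisons run the matching tests", {
  set.seed(3)
  v <- c(rnorm(8, 0), rnorm(8, 2))
  g <- rep(c("CTRL", "TBI"), each = 8)
  res <- compare_groups(v, g)
  expect_equal(res$test, "t-test")
  expect_lt(res$p_value, 0.01)
  # a clearly non-normal (two-point) group drops to the rank branch
  set.seed(4)
  v2 <- c(rnorm(10), rnorm(10, 3), rep(c(0, 5), 5))
  g2 <- rep(letters[1:3], each = 10)
  res2 <- compare_groups(v2, g2)
  expect_equal(res2$branch, "nonparametric")
  expect_equal(res2$test, "Kruskal-Wallis")
  expect_true(all(res2$posthoc$p_adjusted >= res2$posthoc$p_unadjusted))
})

test_that("planted expression effects are recovered with power and low bias", {
  est <- numeric(200); rej <- logical(200)
  for (s in 1:200) {
    tb <- simulate_ct_table("MAP2", 6, 6, c(MAP2 = -1.5),
                            ct_noise_sd = 0.3, seed = 30000 + s)
    fc <- delta_delta_ct(tb, ctrl_group = "CTRL")
    est[s] <- mean(fc$log2fc[fc$group == "TBI"])
    rej[s] <- t.test(log2fc ~ group, data = fc)$p.value < 0.05
  }
  expect_lt(abs(mean(est) + 1.5), 0.1)
  expect_gte(mean(rej), 0.8)
})
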