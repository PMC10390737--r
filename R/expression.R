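#' Delta-delta-Ct relative expression
#'
#' For each sample and target gene, `dCt = Ct(gene) - Ct(reference)`;
#' `ddCt = dCt - mean(dCt over control-group samples)` per gene;
#' `log2FC = -ddCt` (so the control-group mean log2FC is 0 by construction)
#' and `fold_change = 2^log2FC`.
#'
#' @param records data.frame with `sample_id`, `group`, `gene`, `ct` and
#'   either an `is_reference` column or the `reference_gene` argument.
#' @param ctrl_group control group label; default `"CTRL"`.
#' @param reference_gene reference gene name (overrides `is_reference`).
#' @return data.frame: `sample_id`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `log2fc`, `fold_change`.
#' @export
delta_delta_ct <- function(records, ctrl_group = "CTRL",
                           reference_gene = NULL) {
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(records)))
    stop("records needs columns: ", paste(req, collapse = ", "))
  if (is.null(reference_gene)) {
    if (!"is_reference" %in% names(records))
      stop("supply reference_gene or an is_reference column")
    refs <- unique(records$gene[records$is_reference])
    if (length(refs) != 1L) stop("expected exactly one reference gene")
    reference_gene <- refs
  }
  ref <- records[records$gene == reference_gene, ]
  samples <- unique(records$sample_id)
  missing_ref <- setdiff(samples, ref$sample_id)
  if (length(missing_ref))
    stop("missing reference-gene Ct for sample(s): ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  tgt <- records[records$gene != reference_gene, , drop = FALSE]
  if (!any(tgt$group == ctrl_group))
    stop("no samples in control group '", ctrl_group, "'")
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample_id]
  out <- lapply(split(tgt, tgt$gene), function(g) {
    ctrl <- g$delta_ct[g$group == ctrl_group]
    if (length(ctrl) == 0)
      stop("gene ", g$gene[1], " has no control samples")
    g$delta_delta_ct <- g$delta_ct - mean(ctrl)
    g$log2fc <- -g$delta_delta_ct
    g$fold_change <- 2^g$log2fc
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("sample_id", "group", "gene", "delta_ct", "delta_delta_ct",
          "log2fc", "fold_change")]
}

#' Normality-gated choice between parametric and rank tests
#'
#' Shapiro-Wilk per group at `alpha`; all groups passing selects the
#' parametric branch (t-test / ANOVA), any failure the rank-based branch
#' (Mann-Whitney / Kruskal-Wallis). A group whose values are all identical
#' cannot be normal and fails the gate.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @param alpha gate level; default 0.05.
#' @return list with `branch` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (named per-group p-values).
#' @export
choose_test <- function(values, groups, alpha = 0.05) {
  sp <- split(values, groups)
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 3))
    stop("insufficient data: every group needs >= 3 values for the ",
         "normality gate (smallest group has ", min(ns), ")")
  pvals <- vapply(sp, function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }, numeric(1))
  list(branch = if (all(pvals > alpha)) "parametric" else "nonparametric",
       shapiro_p = pvals)
}

#' Omnibus ANOVA with Tukey or Sidak post-hoc comparisons
#'
#' One-way ANOVA on a single factor, or two-way (e.g. region x treatment)
#' ANOVA with type-II sums of squares for unbalanced designs. Post-hoc
#' pairwise comparisons use the named procedure on the model's estimated
#' marginal means; both unadjusted and adjusted p-values are reported. For
#' two-way designs the comparisons are between levels of `factor1` within
#' each level of `factor2`.
#'
#' @param data data.frame.
#' @param response name of the response column.
#' @param factor1 primary factor (compared in the post-hoc step).
#' @param factor2 optional second factor; selects the two-way design.
#' @param posthoc `"tukey"`, `"sidak"`, or `"none"` (omnibus only, e.g. for
#'   simulation loops).
#' @return list of class `group_test`: `design`, `anova` (data.frame of
#'   effects: `term`, `df`, `statistic`, `p_value`), `posthoc` (data.frame:
#'   `contrast`, `estimate`, `p_unadjusted`, `p_adjusted`), `posthoc_method`.
#' @export
omnibus_posthoc <- function(data, response, factor1, factor2 = NULL,
                            posthoc = c("tukey", "sidak", "none")) {
  posthoc <- match.arg(posthoc)
  data[[factor1]] <- factor(data[[factor1]])
  if (nlevels(data[[factor1]]) < 2) stop("factor1 needs >= 2 levels")
  prs_adj <- prs_un <- NULL
  if (is.null(factor2)) {
    fml <- stats::reformulate(factor1, response)
    fit <- stats::aov(fml, data = data)
    sm <- summary(fit)[[1]]
    anova_tab <- data.frame(
      term = trimws(rownames(sm))[1],
      df = sm[["Df"]][1],
      statistic = sm[["F value"]][1],
      p_value = sm[["Pr(>F)"]][1])
    if (posthoc != "none") {
      emm <- emmeans::emmeans(fit, stats::reformulate(factor1))
      prs_adj <- summary(emmeans::contrast(emm, "pairwise"), adjust = posthoc)
      prs_un <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
    }
    design <- "one-way"
  } else {
    data[[factor2]] <- factor(data[[factor2]])
    fml <- stats::as.formula(paste(response, "~", factor1, "*", factor2))
    fit <- stats::lm(fml, data = data)
    a2 <- car::Anova(fit, type = 2)
    keep <- rownames(a2) != "Residuals"
    anova_tab <- data.frame(
      term = rownames(a2)[keep],
      df = a2$Df[keep],
      statistic = a2$`F value`[keep],
      p_value = a2$`Pr(>F)`[keep])
    if (posthoc != "none") {
      emm <- emmeans::emmeans(
        fit, stats::as.formula(paste("~", factor1, "|", factor2)))
      prs_adj <- summary(emmeans::contrast(emm, "pairwise"), adjust = posthoc)
      prs_un <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
    }
    design <- "two-way"
  }
  ph <- NULL
  if (!is.null(prs_adj)) {
    ph <- data.frame(
      contrast = as.character(prs_adj$contrast),
      estimate = prs_adj$estimate,
      p_unadjusted = prs_un$p.value,
      p_adjusted = pmin(1, prs_adj$p.value))
    if (!is.null(factor2)) ph$within <- as.character(prs_adj[[factor2]])
  }
  structure(list(design = design, anova = anova_tab, posthoc = ph,
                 posthoc_method = posthoc, fit = fit),
            class = "group_test")
}

#' Gated two-or-more group comparison
#'
#' Applies the Shapiro-Wilk gate ([choose_test()]), then the matching test:
#' two groups get Welch's t-test or the Mann-Whitney U test; three or more
#' get one-way ANOVA with Tukey post-hoc or the Kruskal-Wallis test with
#' Sidak-adjusted pairwise Mann-Whitney comparisons.
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @param alpha gate level for the normality gate.
#' @param var_equal use the pooled-variance t-test for two groups.
#' @return list: `branch`, `test`, `statistic`, `p_value`, `posthoc`
#'   (data.frame or NULL), `shapiro_p`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, var_equal = TRUE) {
  gate <- choose_test(values, groups, alpha = alpha)
  groups <- factor(groups)
  k <- nlevels(groups)
  posthoc <- NULL
  if (k == 2) {
    if (gate$branch == "parametric") {
      tt <- stats::t.test(values ~ groups, var.equal = var_equal)
      res <- list(test = "t-test", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    } else {
      wt <- stats::wilcox.test(values ~ groups, exact = FALSE)
      res <- list(test = "Mann-Whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value)
    }
  } else {
    if (gate$branch == "parametric") {
      ob <- omnibus_posthoc(data.frame(y = values, g = groups), "y", "g",
                            posthoc = "tukey")
      res <- list(test = "one-way ANOVA",
                  statistic = ob$anova$statistic[1],
                  p_value = ob$anova$p_value[1])
      posthoc <- ob$posthoc
    } else {
      kw <- stats::kruskal.test(values, groups)
      res <- list(test = "Kruskal-Wallis",
                  statistic = unname(kw$statistic), p_value = kw$p.value)
      lev <- levels(groups)
      prs <- utils::combn(lev, 2)
      m <- ncol(prs)
      ph <- apply(prs, 2, function(pr) {
        w <- stats::wilcox.test(values[groups == pr[1]],
                                values[groups == pr[2]], exact = FALSE)
        c(p = w$p.value)
      })
      posthoc <- data.frame(
        contrast = apply(prs, 2, paste, collapse = " - "),
        p_unadjusted = as.numeric(ph),
        p_adjusted = pmin(1, 1 - (1 - as.numeric(ph))^m))
    }
  }
  c(list(branch = gate$branch, shapiro_p = gate$shapiro_p), res,
    list(posthoc = posthoc))
}
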