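# Method-agreement and group-comparison statistics used to validate the
# volumetry: Bland-Altman agreement, Shapiro-Wilk-gated group tests, and
# two-tailed Spearman correlation with the Chan strength labels.

#' Bland-Altman agreement between two measurement methods
#'
#' Paired differences d = a - b; bias = mean(d); limits of agreement =
#' bias +/- 1.96 * SD(d) with the sample (n - 1) standard deviation.
#'
#' @param a,b Paired measurements (same subjects, same order, length >= 2).
#' @return An `agreement_result`: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`, plus the per-pair `(mean, difference)` coordinates for plotting.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    ct_error("bland_altman: length mismatch", "ct_usage_error")
  if (length(a) < 2L)
    ct_error("bland_altman: need at least 2 pairs", "ct_usage_error")
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)              # n - 1 denominator
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    n = length(d), means = (a + b) / 2, diffs = d
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d)\n  bias %.4g, SD of differences %.4g\n  limits of agreement [%.4g, %.4g]\n",
    x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with the bias and
#' the two limits of agreement drawn as horizontal lines.
#'
#' @param x An `agreement_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_result <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = "Mean of methods", ylab = "Difference (a - b)",
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Normality-gated group comparison
#'
#' Each group is screened with the Shapiro-Wilk test at `alpha`. Two groups:
#' two-sample t test if both pass, otherwise a two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test. Three or more groups: one-way ANOVA if all pass,
#' otherwise Kruskal-Wallis. The gate outcome and the chosen test are part of
#' the result rather than hidden.
#'
#' @param groups Named list of numeric vectors, each of length >= 3.
#' @param paired For two groups, use the paired variants (paired t /
#'   Wilcoxon signed-rank). Default `FALSE`.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return A `group_test_result`: `test_name` (one of `mann_whitney_u`,
#'   `t_test`, `anova`, `kruskal_wallis` and their paired variants),
#'   `statistic`, `p_value`, per-group sizes and normality verdicts.
#' @export
compare_groups <- function(groups, paired = FALSE, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    ct_error("compare_groups: need a list of >= 2 groups", "ct_usage_error")
  groups <- lapply(groups, as.numeric)
  ns <- lengths(groups)
  if (any(ns < 3L))
    ct_error("insufficient group size: every group needs n >= 3",
             "ct_usage_error")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  sw_p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(0)     # constant group: not normal
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  normal <- sw_p > alpha
  k <- length(groups)
  if (k == 2L) {
    if (all(normal)) {
      ht <- stats::t.test(groups[[1]], groups[[2]], paired = paired,
                          var.equal = FALSE)
      test_name <- if (paired) "paired_t_test" else "t_test"
    } else {
      ht <- stats::wilcox.test(groups[[1]], groups[[2]], paired = paired,
                               alternative = "two.sided", exact = FALSE,
                               correct = TRUE)
      test_name <- if (paired) "wilcoxon_signed_rank" else "mann_whitney_u"
    }
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(labels, ns), levels = labels)
    if (all(normal)) {
      fit <- stats::aov(values ~ fac)
      tab <- stats::anova(fit)
      statistic <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
      test_name <- "anova"
    } else {
      ht <- stats::kruskal.test(values, fac)
      statistic <- unname(ht$statistic); p <- ht$p.value
      test_name <- "kruskal_wallis"
    }
  }
  structure(list(
    test_name = test_name, statistic = statistic, p_value = p,
    groups = data.frame(label = labels, n = as.integer(ns),
                        shapiro_p = sw_p, normal = normal, row.names = NULL),
    alpha = alpha, paired = paired
  ), class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Group comparison: %s (statistic %.4g, p = %.4g)\n",
              x$test_name, x$statistic, x$p_value))
  cat(sprintf("  normality gate (Shapiro-Wilk, alpha %.2g): %s\n", x$alpha,
              paste(sprintf("%s n=%d %s", x$groups$label, x$groups$n,
                            ifelse(x$groups$normal, "normal", "non-normal")),
                    collapse = "; ")))
  invisible(x)
}

#' Strength label for a correlation coefficient (Chan scale)
#'
#' `|r|` = 1 perfect, >= 0.8 very strong, >= 0.6 moderate, >= 0.3 fair,
#' >= 0.1 weak, else negligible.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @return One of `"perfect"`, `"very_strong"`, `"moderate"`, `"fair"`,
#'   `"weak"`, `"negligible"`.
#' @export
chan_label <- function(r) {
  a <- abs(r)
  if (a > 1 + 1e-12) ct_error("correlation outside [-1, 1]", "ct_usage_error")
  if (a >= 1) "perfect"
  else if (a >= 0.8) "very_strong"
  else if (a >= 0.6) "moderate"
  else if (a >= 0.3) "fair"
  else if (a >= 0.1) "weak"
  else "negligible"
}

#' Two-tailed Spearman correlation with Chan labels
#'
#' @param x,y Paired numeric vectors, length >= 4, neither constant.
#' @return A `correlation_result`: `r` (Spearman's rho), two-tailed
#'   `p_value`, and the Chan strength `label`.
#' @export
correlate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 4L)
    ct_error("correlate: need paired vectors of length >= 4", "ct_usage_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ct_error("undefined correlation: constant input vector", "ct_usage_error")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided",
                                         exact = FALSE))
  r <- unname(ht$estimate)
  # rank arithmetic can leave 1 - eps for an exact monotone relation
  if (abs(r) > 1 - 1e-9) r <- sign(r)
  structure(list(r = r, p_value = ht$p.value, label = chan_label(r),
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman correlation: r = %.4g (%s), two-tailed p = %.4g, n = %d\n",
              x$r, x$label, x$p_value, x$n))
  invisible(x)
}
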