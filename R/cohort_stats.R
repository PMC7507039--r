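#' Statistical test result container
#'
#' Uniform return type for the cohort statistics: test name, statistic,
#' degrees of freedom (when defined), two-sided p-value, an effect
#' summary, and free-text notes recording gate decisions (which branch a
#' dispatcher took, minimum expected counts, and similar).
#'
#' @param method Test name.
#' @param statistic Test statistic (may be `NA`).
#' @param p_value Two-sided p-value in `[0, 1]`.
#' @param df Degrees of freedom, `NA` when not defined.
#' @param estimate Named effect summary (mean difference, odds ratio, rho...).
#' @param notes Character vector of annotations.
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(method, statistic, p_value, df = NA_real_,
                        estimate = NULL, notes = character(0)) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12),
            is.na(df) || df > 0)
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(min(p_value, 1)),
                 estimate = estimate, notes = notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %s\n", x$method,
              ifelse(is.na(x$statistic), "NA", sprintf("%.4g", x$statistic)),
              ifelse(is.na(x$df), "-", sprintf("%.4g", x$df)),
              format_p(x$p_value)))
  if (!is.null(x$estimate))
    cat("  estimate:", paste(names(x$estimate), signif(unlist(x$estimate), 4),
                             sep = " = ", collapse = ", "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Format a p-value in report style
#'
#' Three-decimal clinical style: `p = .017`, with `p < .001` below that
#' resolution. Full precision is always retained on the `stat_result`
#' itself; formatting happens only at the reporting boundary.
#'
#' @param p P-value.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.0005) return("< .001")
  paste0("= ", sub("^0", "", sprintf("%.3f", p)))
}

#' Two-sample t test from summary statistics
#'
#' Pooled or Welch two-sample t test computed from group means, SDs and
#' sizes alone — the form needed to reproduce published comparisons when
#' only summary statistics are printed.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param variant `"pooled"` (equal variances) or `"welch"`
#'   (Satterthwaite df).
#' @return A [stat_result()] with the mean difference as estimate.
#' @examples
#' ttest_from_summary(37.7, 10.2, 23, 50.0, 10.4, 10)
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  diff <- mean2 - mean1
  if (sd1 == 0 && sd2 == 0) {
    if (diff == 0)
      return(stat_result("t-test (degenerate)", 0, 1, n1 + n2 - 2,
                         estimate = c(mean_diff = 0),
                         notes = "zero variance in both groups, equal means"))
    return(stat_result("t-test (degenerate)", Inf, 0, n1 + n2 - 2,
                       estimate = c(mean_diff = diff),
                       notes = "zero variance in both groups"))
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  stat_result(paste0("two-sample t (", variant, ", summary)"), t, p, df,
              estimate = c(mean_diff = diff))
}

#' Two-sample t test on raw data
#'
#' Wraps [stats::t.test()]; the pooled variant is algebraically identical
#' to [ttest_from_summary()] applied to the samples' own summaries.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return A [stat_result()].
#' @export
ttest_two_sample <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(ttest_from_summary(mean(x), 0, length(x), mean(y), 0, length(y),
                              variant))
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  stat_result(paste0("two-sample t (", variant, ")"),
              -ht$statistic, ht$p.value, ht$parameter,
              estimate = c(mean_diff = mean(y) - mean(x)))
}

#' Levene / Brown-Forsythe test for equality of variances
#'
#' One-way Levene test on the absolute deviations from each group's
#' centre; centre = mean by default (the classical Levene form used by
#' SPSS-style workflows), with `center = "median"` giving the
#' Brown-Forsythe variant. Backed by [car::leveneTest()].
#'
#' @param x,y Numeric samples.
#' @param center `"mean"` or `"median"`.
#' @return A [stat_result()] with the F statistic and (1, n-2) df.
#' @export
levene <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(x) >= 2, length(y) >= 2)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  v <- c(x, y)
  if (isTRUE(all.equal(stats::sd(x), 0)) && isTRUE(all.equal(stats::sd(y), 0)))
    return(stat_result("Levene", 0, 1, length(v) - 2,
                       notes = "no within-group spread"))
  lt <- car::leveneTest(v, g, center = if (center == "mean") mean else median)
  stat_result(paste0("Levene (center = ", center, ")"),
              lt$`F value`[1], lt$`Pr(>F)`[1], lt$Df[2])
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Rank-sum test with midranks for ties. The p-value is exact (full
#' enumeration of the rank-sum distribution) when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used. Reports each
#' group's median and interquartile range, the conventional descriptive
#' pair for non-normal data.
#'
#' @param x,y Numeric samples.
#' @return A [stat_result()]; estimate holds medians and IQRs.
#' @export
wilcoxon_ranksum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  stat_result(paste0("Wilcoxon rank-sum (",
                     if (exact) "exact" else "normal approx.", ")"),
              ht$statistic, ht$p.value,
              estimate = c(median_x = stats::median(x),
                           iqr_x = stats::IQR(x),
                           median_y = stats::median(y),
                           iqr_y = stats::IQR(y)),
              notes = if (ties) "midrank ties" else character(0))
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson `X^2 = sum (O - E)^2 / E` with expected counts from the
#' margins and `(r-1)(c-1)` degrees of freedom, without continuity
#' correction. The minimum expected cell count is recorded in the notes
#' (the usual validity check before preferring an exact test).
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2.
#' @return A [stat_result()].
#' @examples
#' chi_square_rxc(matrix(c(15, 2, 8, 8), 2))
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2,
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result("Pearson chi-square", ht$statistic, ht$p.value, ht$parameter,
              notes = sprintf("min expected count %.2f", min(ht$expected)))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact conditional test with fixed margins. The two-sided p-value sums
#' the hypergeometric probabilities of every table no more probable than
#' the observed one (with a `1 + 1e-7` tolerance factor for ties); the
#' one-sided p and the conditional-MLE odds ratio are reported alongside.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return A [stat_result()]; `estimate` holds the odds ratio and the
#'   one-sided p.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(stat_result("Fisher exact", NA_real_, 1,
                       notes = "zero margin: table is degenerate, p = 1"))
  ht <- stats::fisher.test(table)
  p_less <- stats::fisher.test(table, alternative = "less")$p.value
  p_greater <- stats::fisher.test(table, alternative = "greater")$p.value
  stat_result("Fisher exact", NA_real_, ht$p.value,
              estimate = c(odds_ratio = unname(ht$estimate),
                           p_one_sided = min(p_less, p_greater)))
}

#' Spearman rank correlation
#'
#' Midrank-based rank correlation with the t-approximation p-value
#' (`t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` df).
#'
#' @param x,y Paired numeric vectors.
#' @return A [stat_result()]; `estimate` holds `rho`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
    tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  stat_result("Spearman rank correlation", tstat, p, n - 2,
              estimate = c(rho = rho))
}

#' Normality- and variance-gated group comparison
#'
#' Dispatcher reproducing the SPSS-style analysis plan: for a continuous
#' variable, a Shapiro-Wilk gate (alpha = .05, per group) decides between
#' the t test and the Wilcoxon rank-sum test; when the t branch is taken,
#' a Levene gate (alpha = .05, centre = mean) chooses pooled vs Welch.
#' For a categorical variable the groups are cross-tabulated and tested by
#' Pearson chi-square without continuity correction; for a 2 x 2 table
#' Fisher's exact test is computed alongside and carried in the notes.
#' By default the chi-square p is the primary result even when an
#' expected count falls below 5 (`small_expected = "chi_square"`), which
#' reproduces SPSS-style published contingency p-values;
#' `small_expected = "fisher"` promotes the exact test to primary for
#' small-expected-count 2 x 2 tables instead. Every gate decision is
#' recorded in the notes.
#'
#' @param cohort A data frame (e.g. from [generate_cohort()]).
#' @param variable Column to compare (numeric => continuous, otherwise
#'   categorical).
#' @param grouping Column defining the groups.
#' @param levels Optional two group levels to restrict the comparison to.
#' @param small_expected Which test leads for a 2 x 2 table with an
#'   expected count below 5: `"chi_square"` (default) or `"fisher"`.
#' @return A [stat_result()].
#' @examples
#' ch <- generate_cohort(1)
#' compare_groups(ch, "age", "aetiology",
#'                levels = c("vasculitis", "atherosclerosis"))
#' @export
compare_groups <- function(cohort, variable, grouping, levels = NULL,
                           small_expected = c("chi_square", "fisher")) {
  small_expected <- match.arg(small_expected)
  stopifnot(variable %in% names(cohort), grouping %in% names(cohort))
  g <- cohort[[grouping]]
  v <- cohort[[variable]]
  if (!is.null(levels)) {
    keep <- g %in% levels
    g <- factor(g[keep], levels = levels)
    v <- v[keep]
  } else g <- factor(g)
  if (nlevels(g) < 2) stop("need at least two groups")
  keep <- !is.na(v) & !is.na(g)
  g <- droplevels(g[keep]); v <- v[keep]

  if (is.numeric(v) && !is.logical(v)) {
    if (nlevels(g) != 2)
      stop("continuous comparison supports exactly two groups")
    x <- v[g == levels(g)[1]]; y <- v[g == levels(g)[2]]
    sw_p <- vapply(list(x, y), function(s)
      if (length(unique(s)) < 3) 0 else stats::shapiro.test(s)$p.value,
      numeric(1))
    if (all(sw_p > 0.05)) {
      lv <- levene(x, y)
      variant <- if (lv$p_value < 0.05) "welch" else "pooled"
      res <- ttest_two_sample(x, y, variant)
      res$notes <- c(res$notes,
                     sprintf("branch: t-test (%s)", variant),
                     sprintf("Shapiro-Wilk p = %.3f / %.3f", sw_p[1], sw_p[2]),
                     sprintf("Levene p = %.3f", lv$p_value))
    } else {
      res <- wilcoxon_ranksum(x, y)
      res$notes <- c(res$notes, "branch: wilcoxon",
                     sprintf("Shapiro-Wilk p = %.3f / %.3f", sw_p[1], sw_p[2]))
    }
    return(res)
  }

  tab <- table(g, factor(v))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- chi_square_rxc(tab)
  is2x2 <- all(dim(tab) == c(2, 2))
  fis <- if (is2x2) fisher_exact_2x2(tab) else NULL
  small <- any(expected < 5)
  if (is2x2 && small && small_expected == "fisher") {
    res <- fis
    res$notes <- c(res$notes, "branch: fisher (expected count < 5)",
                   sprintf("chi-square p = %.4f", chi$p_value))
  } else {
    res <- chi
    res$notes <- c(res$notes, "branch: chi-square",
                   if (small) "an expected count is below 5",
                   if (!is.null(fis))
                     sprintf("Fisher exact p = %.4f", fis$p_value))
  }
  res
}
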