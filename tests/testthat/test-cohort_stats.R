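test_that("summary t test reproduces hand algebra in both variants", {
  # pooled: frozen against the first-principles formula in the helper
  r <- ttest_from_summary(37.7, 10.2, 23, 50.0, 10.4, 10)
  expect_equal(r$p_value, pooled_t_p(37.7, 10.2, 23, 50.0, 10.4, 10),
               tolerance = 1e-12)
  expect_equal(r$df, 31)
  # welch on the same summaries: direct evaluation of the Satterthwaite
  # formulas distinguishes the variants
  w <- ttest_from_summary(37.7, 10.2, 23, 50.0, 10.4, 10, "welch")
  expect_equal(w$statistic, 3.1405, tolerance = 1e-4)
  expect_equal(w$df, 16.893, tolerance = 1e-3)
  expect_equal(w$p_value, 0.005999, tolerance = 1e-4)
  # identical summaries: t = 0, p = 1
  e <- ttest_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(e$statistic, 0)
  expect_equal(e$p_value, 1)
  # degenerate zero-variance equal-mean case
  d <- ttest_from_summary(5, 0, 10, 5, 0, 10)
  expect_equal(d$p_value, 1)
  expect_match(paste(d$notes, collapse = " "), "zero variance")
})

test_that("raw-data pooled t equals the summary-statistic t (algebraic identity)", {
  set.seed(2)
  x <- rnorm(12, 10, 2); y <- rnorm(9, 12, 3)
  raw <- ttest_two_sample(x, y, "pooled")
  summ <- ttest_from_summary(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y), "pooled")
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(ttest_two_sample(x, x)$p_value, 1)
})

test_that("two-sample t detects the acute vs no-event separation reliably", {
  # power check at the Ktrans group summaries: with means 0.098 vs 0.007
  # and SDs 0.038 / 0.001 at n = 10 each, the effect is so large that
  # essentially every replicate is significant
  set.seed(10)
  hits <- 0L
  for (i in 1:500) {
    x <- rnorm(10, 0.098, 0.038); y <- rnorm(10, 0.007, 0.001)
    if (ttest_two_sample(x, y, "welch")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.99)
})

test_that("pooled t holds its nominal type-I error under the null", {
  # 10,000 seeded replicates of equal-variance normal samples via the
  # summary formula; rejection rate must sit at alpha = .05 +/- .01
  set.seed(123)
  n <- 12
  x <- matrix(rnorm(10000 * n), 10000)
  y <- matrix(rnorm(10000 * n), 10000)
  p <- pooled_t_p(rowMeans(x), apply(x, 1, sd), n,
                  rowMeans(y), apply(y, 1, sd), n)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("Levene test: degenerate input, calibration and power", {
  x <- c(1, 2, 3, 4)
  d <- levene(x, x)
  expect_equal(d$statistic, 0, tolerance = 1e-12)
  expect_equal(d$p_value, 1, tolerance = 1e-12)
  # type-I error under equal variances; the median-centred
  # (Brown-Forsythe) form is the calibrated variant, the mean-centred
  # default trades a known small-sample liberality for SPSS fidelity
  set.seed(5)
  rej <- mean(replicate(1000, {
    levene(rnorm(20), rnorm(20), center = "median")$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
  set.seed(5)
  rej_mean <- mean(replicate(1000, {
    levene(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_lt(abs(rej_mean - 0.05), 0.05)
  # power under a 3x scale shift
  set.seed(6)
  rej2 <- mean(replicate(200, {
    levene(rnorm(50), rnorm(50, sd = 3))$p_value < 0.05
  }))
  expect_gt(rej2, 0.9)
  # both centre choices are accepted
  expect_s3_class(levene(rnorm(10), rnorm(10), center = "median"),
                  "stat_result")
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and approximation", {
  # smallest extreme configuration: enumeration gives 2/6
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_match(r$method, "exact")
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # exact route agrees with the brute-force enumeration oracle
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(wilcoxon_ranksum(x, y)$p_value, wilcox_enum_p(x, y),
                 tolerance = 1e-9)
  }
  # n = 8 + 8: normal approximation tracks the exact p within .01
  set.seed(9)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  exact_p <- wilcoxon_ranksum(x, y)$p_value         # combined n = 16 <= 20
  approx_p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(exact_p - approx_p), 0.01)
  # ties force the midrank approximation and are noted
  rt <- wilcoxon_ranksum(c(1, 1, 2), c(2, 3, 3))
  expect_match(paste(rt$notes, collapse = " "), "ties")
})

test_that("chi-square reproduces the published contingency p-values", {
  r1 <- chi_square_rxc(matrix(c(15, 2, 8, 8), 2))
  expect_equal(round(r1$p_value, 3), 0.017)
  expect_equal(r1$statistic, 5.70, tolerance = 0.01)
  r2 <- chi_square_rxc(matrix(c(15, 1, 8, 2), 2))
  expect_equal(round(r2$p_value, 3), 0.286)
  expect_equal(r2$statistic, 1.14, tolerance = 0.01)
  # balanced table: no association at all
  r3 <- chi_square_rxc(matrix(10, 2, 2))
  expect_equal(r3$statistic, 0, ignore_attr = TRUE)
  expect_equal(r3$p_value, 1)
  expect_error(chi_square_rxc(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  # monotonicity: sliding mass off the diagonal at fixed margins can only
  # shrink the p-value
  p_seq <- vapply(0:5, function(k)
    chi_square_rxc(matrix(c(10 + k, 10 - k, 10 - k, 10 + k), 2))$p_value,
    numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  # worked examples enumerated by hand
  expect_equal(fisher_exact_2x2(matrix(c(15, 1, 8, 2), 2))$p_value,
               0.538, tolerance = 1e-3)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  # zero margin is degenerate, not an error
  z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))
  expect_equal(z$p_value, 1)
  expect_match(paste(z$notes, collapse = " "), "zero margin")
  # oracle sweep: 200 random tables with N <= 30
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r <- fisher_exact_2x2(tab)
    expect_equal(r$p_value, fisher_enum_p(tab), tolerance = 1e-9)
    expect_gte(r$p_value, r$estimate[["p_one_sided"]] - 1e-12)
  }
})

test_that("Spearman correlation matches the rank formula", {
  expect_equal(spearman(1:6, (1:6)^3)$estimate[["rho"]], 1)
  expect_equal(spearman(1:6, -(1:6)^3)$estimate[["rho"]], -1)
  r <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate[["rho"]], 0.6, tolerance = 1e-12)
  expect_equal(r$estimate[["rho"]],
               spearman_enum_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("dispatcher takes the documented branches", {
  ch <- generate_cohort(1)
  # Table-1-style smoking contrast: contingency branch, chi-square leads
  r <- compare_groups(ch, "smoking", "aetiology",
                      levels = c("vasculitis", "atherosclerosis"))
  expect_match(paste(r$notes, collapse = " "), "chi-square")
  expect_equal(round(r$p_value, 3), 0.017)
  # the exact-test-preferred rule is available as a switch
  rf <- compare_groups(ch, "smoking", "aetiology",
                       levels = c("vasculitis", "atherosclerosis"),
                       small_expected = "fisher")
  expect_match(rf$method, "Fisher")
  # clean normal data lands in the t branch
  set.seed(12)
  d <- data.frame(v = c(rnorm(15, 10), rnorm(15, 11)),
                  g = rep(c("a", "b"), each = 15))
  rn <- compare_groups(d, "v", "g")
  expect_match(paste(rn$notes, collapse = " "), "branch: t-test")
  # heavily skewed data lands in the wilcoxon branch most of the time
  set.seed(13)
  wil <- mean(replicate(200, {
    d <- data.frame(v = c(rlnorm(15, sd = 1.5), rlnorm(15, sd = 1.5)),
                    g = rep(c("a", "b"), each = 15))
    grepl("wilcoxon", paste(compare_groups(d, "v", "g")$notes,
                            collapse = " "))
  }))
  expect_gte(wil, 0.9)
  # determinism: same cohort in, identical decision and p out
  r2 <- compare_groups(ch, "smoking", "aetiology",
                       levels = c("vasculitis", "atherosclerosis"))
  expect_identical(r$p_value, r2$p_value)
  expect_identical(r$notes, r2$notes)
})

test_that("all reported p-values live in [0, 1] and format correctly", {
  expect_equal(format_p(0.01749), "= .017")
  expect_equal(format_p(0.0004), "< .001")
  expect_equal(format_p(1), "= 1.000")
  expect_error(stat_result("x", 1, 1.5))
  expect_error(stat_result("x", 1, 0.5, df = -2))
})
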