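test_that("normality gate keeps its nominal operating characteristics", {
  set.seed(101)
  calls <- replicate(500, as.character(normality_gate(rnorm(27))))
  expect_gte(mean(calls == "normal"), 0.90)
  set.seed(102)
  expect_equal(as.character(normality_gate(rexp(200))), "non_normal")
  expect_warning(g <- normality_gate(rep(3, 10)), "constant")
  expect_equal(as.character(g), "non_normal")
})

test_that("paired test gates between t and Wilcoxon and handles degeneracy", {
  x <- c(10, 12, 14, 16, 18, 20, 25)
  ps <- paired_sample(x, x)
  res <- paired_test(ps)
  expect_equal(res$p_value, 1)
  expect_equal(res$note, "all differences zero")
  set.seed(7)
  y <- x + rnorm(7, 0, 0.5)
  expect_equal(paired_test(paired_sample(x, y), gate = "normal")$test_used, "t")
  expect_equal(paired_test(paired_sample(x, y), gate = "non_normal")$test_used,
               "wilcoxon")
  # the t branch agrees with the one-sample t on the differences
  expect_equal(paired_test(paired_sample(x, y), gate = "normal")$p_value,
               t.test(y - x)$p.value)
})

test_that("Bonferroni thresholds reproduce the familywise levels", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 34), 0.05 / 34)
  expect_equal(round(bonferroni_threshold(0.05, 34), 4), 0.0015)
  expect_equal(round(bonferroni_threshold(0.05, 13), 3), 0.004)
  expect_equal(round(bonferroni_threshold(0.05, 6), 3), 0.008)
  expect_equal(round(bonferroni_threshold(0.05, 3), 3), 0.017)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("bias statistics reproduce SED and t-based CI arithmetic", {
  # construct differences with exact mean 0.7 and sd 4.55, n = 27
  base <- scale(seq_len(27))[, 1]
  d <- 0.7 + base * 4.55
  ps <- paired_sample(rep(0, 27), d)
  bs <- bias_stats(ps)
  expect_equal(bs$mean_diff, 0.7)
  expect_equal(bs$sd_diff, 4.55)
  expect_equal(bs$sed, 4.55 / sqrt(27))
  expect_equal(round(bs$sed, 2), 0.88)
  tq <- qt(0.975, 26)
  expect_equal(bs$ci95, 0.7 + c(-1, 1) * tq * 4.55 / sqrt(27))
  expect_equal(round(bs$ci95, 1), c(-1.1, 2.5))
  # all-equal differences give a point interval
  psc <- paired_sample(c(1, 2, 3), c(3, 4, 5))
  bsc <- bias_stats(psc)
  expect_equal(bsc$mean_diff, 2)
  expect_equal(bsc$sd_diff, 0)
  expect_equal(bsc$ci95, c(2, 2))
})

test_that("Bland-Altman limits are bias +/- 1.96 sd", {
  base <- scale(seq_len(27))[, 1]
  ps <- paired_sample(rep(20, 27), 20 + 0.7 + base * 4.55)
  ba <- bland_altman(ps)
  expect_equal(ba$bias, 0.7)
  expect_equal(ba$loa, c(0.7 - 1.96 * 4.55, 0.7 + 1.96 * 4.55))
  expect_equal(round(ba$loa, 2), c(-8.22, 9.62))
  expect_equal(nrow(ba$pairs), 27)
  x <- c(5, 6, 7)
  ident <- bland_altman(paired_sample(x, x))
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa, c(0, 0))
})

test_that("LoA of normal differences cover about 95% at large n", {
  set.seed(314)
  n <- 20000
  d <- rnorm(n, 1.5, 2.5)
  ps <- paired_sample(rep(0, n), d)
  ba <- bland_altman(ps)
  cover <- mean(d >= ba$loa[1] & d <= ba$loa[2])
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("RMA regression is the sd ratio with the sign of r", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rma_regression(paired_sample(x, x)),
               list(slope = 1, intercept = 0))
  set.seed(5)
  a <- rnorm(40); b <- 3 - 2 * a + rnorm(40, 0, 0.3)
  fit <- rma_regression(paired_sample(a, b))
  expect_equal(fit$slope, sign(cor(a, b)) * sd(b) / sd(a))
  expect_lt(fit$slope, 0)
  # scale equivariance: scaling the estimate by k divides the slope by k
  fit2 <- rma_regression(paired_sample(2 * a, b))
  expect_equal(fit2$slope, fit$slope / 2)
  # axis exchange inverts the slope (for positive correlation)
  c1 <- rnorm(30); c2 <- c1 + rnorm(30, 0, 0.4)
  f12 <- rma_regression(paired_sample(c1, c2))
  f21 <- rma_regression(paired_sample(c2, c1))
  expect_equal(f12$slope, 1 / f21$slope)
  expect_error(rma_regression(paired_sample(rep(1, 5), x)), "zero-variance")
})

test_that("correlation bands follow the printed thresholds", {
  expect_equal(correlation_band(0.75), "very strong")
  expect_equal(correlation_band(0.25), "weak")
  expect_equal(correlation_band(c(1, 0.69, 0.35, 0.1, -0.13)),
               c("very strong", "strong", "moderate", "none", "none"))
  x <- c(1, 2, 3, 4, 5, 6)
  r <- correlation(paired_sample(x, 2 * x + 1), gate = "normal")
  expect_equal(r$coefficient, 1)
  expect_equal(r$band, "very strong")
  expect_equal(r$type, "pearson")
  rs <- correlation(paired_sample(x, x^3), gate = "non_normal")
  expect_equal(rs$type, "spearman")
  expect_equal(rs$coefficient, 1)
  expect_error(correlation(paired_sample(rep(2, 6), x), gate = "non_normal"),
               "tie-only")
})

test_that("ICC modes behave as shift-sensitive vs shift-invariant", {
  x <- c(8, 12, 15, 19, 23, 27, 30)
  ident <- list(a = icc(paired_sample(x, x), "absolute"),
                c = icc(paired_sample(x, x), "consistency"))
  expect_equal(ident$a$icc, 1)
  expect_equal(ident$c$icc, 1)
  shifted <- paired_sample(x, x + 5)
  expect_equal(icc(shifted, "consistency")$icc, 1)
  expect_lt(icc(shifted, "absolute")$icc, 1)
  expect_error(icc(paired_sample(rep(1, 6), rep(1, 6))), "zero total variance")
})

test_that("hand-rolled ICC equals the ANOVA mean-squares oracle", {
  set.seed(88)
  for (rep_i in 1:40) {
    n <- sample(5:15, 1)
    x <- rnorm(n, 20, 4)
    y <- x + rnorm(n, 0.8, 1.5)
    ps <- paired_sample(x, y)
    # oracle: two-way ANOVA mean squares via stats::aov
    long <- data.frame(value = c(x, y),
                       subject = factor(rep(seq_len(n), 2)),
                       method = factor(rep(c("a", "b"), each = n)))
    ms <- summary(aov(value ~ subject + method, data = long))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_c <- (msr - mse) / (msr + mse)
    icc_a <- (msr - mse) / (msr + mse + (2 / n) * max(msc - mse, 0))
    expect_equal(icc(ps, "consistency")$icc, icc_c, tolerance = 1e-10)
    expect_equal(icc(ps, "absolute")$icc, icc_a, tolerance = 1e-10)
  }
})

test_that("ICC bands follow the printed scale", {
  expect_equal(icc_band(0.86), "almost perfect")
  expect_equal(icc_band(0.5), "moderate")
  expect_equal(icc_band(-0.27), "poor")
  expect_equal(icc_band(c(0.1, 0.3, 0.7)), c("slight", "fair", "substantial"))
})

test_that("TEM matches hand evaluation and is scale-invariant in relative form", {
  r <- tem(c(10, 20, 30), c(10.2, 19.8, 30.4))
  expect_equal(r$tem_abs, sqrt(0.24 / 6))
  expect_equal(r$tem_abs, 0.2)
  expect_equal(round(r$tem_relative_percent, 2), 1.00)
  expect_equal(tem(c(5, 5), c(5, 5))$tem_relative_percent, 0)
  r10 <- tem(10 * c(10, 20, 30), 10 * c(10.2, 19.8, 30.4))
  expect_equal(r10$tem_relative_percent, r$tem_relative_percent)
  expect_error(tem(c(-1, 1), c(1, -1)), "zero grand mean")
})

test_that("Fisher z intervals are symmetric at zero and shrink with n", {
  ci0 <- fisher_z_icc_ci(0, 30)
  expect_equal(ci0[1], -ci0[2])
  wide <- fisher_z_icc_ci(0.977, 8)
  narrow <- fisher_z_icc_ci(0.977, 1000)
  expect_lt(diff(narrow), diff(wide))
  expect_lt(wide[1], 0.977)  # strongly asymmetric near 1
  expect_gt(0.977 - wide[1], wide[2] - 0.977)
  expect_warning(deg <- fisher_z_icc_ci(1, 30), "degenerate")
  expect_equal(deg, c(1, 1))
})

test_that("paired sample-size formula matches the normal approximation", {
  expect_equal(paired_sample_size(1, 1.8, 0.05, 0.8), 26)
  expect_equal(paired_sample_size(1, 0.9, 0.05, 0.8), 7)
  expect_equal(paired_sample_size(1e6, 1.8, 0.05, 0.8), 2)  # clamped minimum
  expect_error(paired_sample_size(0, 1.8), "delta")
})

test_that("the agreement report assembles the full battery consistently", {
  set.seed(12)
  x <- rnorm(27, 26, 5.9)
  y <- x + rnorm(27, 0.7, 4.55)
  ps <- paired_sample(x, y, family = "FP", equation_id = "hastuti")
  row <- agreement_report(ps, m = 34)
  expect_equal(row$n, 27)
  expect_equal(row$mean_diff, mean(y - x))
  expect_equal(row$loa_upper - row$loa_lower, 2 * 1.96 * sd(y - x))
  expect_equal(row$bonferroni_alpha, 0.05 / 34)
  expect_lte(row$icc_absolute, row$icc_consistency + 1e-12)
  expect_true(row$test_used %in% c("t", "wilcoxon"))
  expect_true(row$icc_abs_band %in% c("poor", "slight", "fair", "moderate",
                                      "substantial", "almost perfect"))
})
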