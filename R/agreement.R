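# Method-comparison battery --------------------------------------------------
#
# Difference convention: diff = reference - estimate, so a positive bias
# means the equation UNDERESTIMATES the reference method. Every report
# carries this convention explicitly.

#' Paired sample of equation estimates and reference values
#'
#' Aligns per-subject estimates with reference measurements, drops
#' incomplete pairs (count recorded) and checks a minimum size of 3.
#'
#' @param estimate numeric vector of equation estimates.
#' @param reference numeric vector of reference (e.g. DXA) values, aligned
#'   by subject.
#' @param family optional family label, one of `"FP"`, `"FM"`, `"LP"`, `"LM"`.
#' @param equation_id optional equation id carried into reports.
#' @return An object of class `paired_sample` with elements `x` (estimate),
#'   `y` (reference), `n`, `n_dropped`, `family`, `equation_id`.
#' @export
paired_sample <- function(estimate, reference, family = NULL, equation_id = NULL) {
  if (length(estimate) != length(reference))
    stop("estimate and reference must have equal length (aligned by subject)")
  keep <- complete.cases(estimate, reference)
  x <- as.numeric(estimate[keep]); y <- as.numeric(reference[keep])
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (!is.null(family)) family <- match.arg(family, c("FP", "FM", "LP", "LM"))
  structure(list(x = x, y = y, n = length(x),
                 n_dropped = sum(!keep), family = family,
                 equation_id = equation_id,
                 convention = "diff = reference - estimate"),
            class = "paired_sample")
}

.diffs <- function(sample) sample$y - sample$x

#' Shapiro-Wilk normality gate
#'
#' Classifies a variable as `"normal"` when the Shapiro-Wilk p-value is at
#' least `alpha`; the downstream paired test and correlation type switch on
#' this gate. A constant vector is classified `"non_normal"` with a warning.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha gate level, default 0.05.
#' @return `"normal"` or `"non_normal"`, with the p-value as attribute
#'   `"p_value"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values")
  if (sd(values) == 0) {
    warning("constant vector: normality gate set to non_normal")
    return(structure("non_normal", p_value = NA_real_))
  }
  p <- shapiro.test(values)$p.value
  structure(if (p >= alpha) "normal" else "non_normal", p_value = p)
}

#' Paired comparison test (t or Wilcoxon, normality-gated)
#'
#' Uses the paired t-test when both variables pass the normality gate and
#' the Wilcoxon signed-rank test otherwise (exact for n <= 25 without ties
#' or zeros, asymptotic with continuity correction above). The one-sample t
#' on the differences and the paired t are the same computation and are
#' implemented once.
#'
#' @param sample a [paired_sample()].
#' @param gate `"normal"`, `"non_normal"` or `NULL` (compute from the data:
#'   normal only if both estimate and reference pass the gate).
#' @param alpha gate level when `gate` is `NULL`.
#' @return List with `p_value`, `test_used` (`"t"` or `"wilcoxon"`),
#'   `gate_x`, `gate_y`, and `note` for degenerate inputs.
#' @export
paired_test <- function(sample, gate = NULL, alpha = 0.05) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- .diffs(sample)
  gx <- gy <- NA_character_
  if (is.null(gate)) {
    gx <- as.character(suppressWarnings(normality_gate(sample$x, alpha)))
    gy <- as.character(suppressWarnings(normality_gate(sample$y, alpha)))
    gate <- if (gx == "normal" && gy == "normal") "normal" else "non_normal"
  }
  gate <- match.arg(gate, c("normal", "non_normal"))
  if (all(d == 0))
    return(list(p_value = 1, test_used = "t", gate_x = gx, gate_y = gy,
                note = "all differences zero"))
  if (sd(d) == 0)
    return(list(p_value = 0, test_used = "t", gate_x = gx, gate_y = gy,
                note = "constant non-zero differences"))
  if (gate == "normal") {
    p <- t.test(d)$p.value
    test <- "t"
  } else {
    exact <- sample$n <= 25 && !any(duplicated(abs(d))) && !any(d == 0)
    p <- suppressWarnings(
      wilcox.test(d, exact = exact, correct = TRUE)$p.value)
    test <- "wilcoxon"
  }
  list(p_value = p, test_used = test, gate_x = gx, gate_y = gy, note = NA_character_)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m number of comparisons in the family, >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 34)
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Bias, SED and confidence interval of the mean difference
#'
#' `sed = sd(diff)/sqrt(n)`; the 95% CI uses the t quantile with n - 1
#' degrees of freedom.
#'
#' @param sample a [paired_sample()].
#' @param conf confidence level, default 0.95.
#' @return List with `mean_diff`, `sd_diff`, `sed`, `ci95 = c(lower, upper)`,
#'   `n`.
#' @export
bias_stats <- function(sample, conf = 0.95) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- .diffs(sample)
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  m <- mean(d); s <- sd(d); sed <- s / sqrt(n)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  list(mean_diff = m, sd_diff = s, sed = sed,
       ci95 = c(m - tq * sed, m + tq * sed), n = n)
}

#' Bland-Altman analysis
#'
#' Limits of agreement `bias +/- 1.96 * sd(diff)` (the conventional normal
#' multiplier, not 2.0 and not t-based), plus the per-subject (mean, diff)
#' pairs for plotting.
#'
#' @param sample a [paired_sample()].
#' @return List with `bias`, `loa = c(lower, upper)` and a data.frame
#'   `pairs` with columns `mean` and `diff`.
#' @export
bland_altman <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- .diffs(sample)
  if (length(d) < 2) stop("need at least 2 pairs")
  b <- mean(d); s <- sd(d)
  list(bias = b, loa = c(b - 1.96 * s, b + 1.96 * s),
       pairs = data.frame(mean = (sample$x + sample$y) / 2, diff = d))
}

#' Reduced major axis (geometric mean) regression
#'
#' Regresses the reference (dependent) on the estimate:
#' `slope = sign(r) * sd(reference)/sd(estimate)`,
#' `intercept = mean(reference) - slope * mean(estimate)`. Ideal agreement
#' is slope 1, intercept 0.
#'
#' @param sample a [paired_sample()].
#' @return List with `slope` and `intercept`.
#' @export
rma_regression <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  sx <- sd(sample$x); sy <- sd(sample$y)
  if (sx == 0 || sy == 0) stop("zero-variance input: RMA regression undefined")
  r <- cor(sample$x, sample$y)
  slope <- sign(r) * sy / sx
  list(slope = slope, intercept = mean(sample$y) - slope * mean(sample$x))
}

#' Correlation with verbal band
#'
#' Pearson when the gate is `"normal"`, Spearman otherwise. Bands:
#' above 0.7 very strong; 0.4-0.69 strong; 0.3-0.39 moderate; 0.2-0.29 weak;
#' below 0.2 (including negative coefficients) none.
#'
#' @param sample a [paired_sample()].
#' @param gate `"normal"`, `"non_normal"` or `NULL` (compute from the data).
#' @param alpha gate level when computing the gate.
#' @return List with `coefficient`, `type` and `band`.
#' @export
correlation <- function(sample, gate = NULL, alpha = 0.05) {
  stopifnot(inherits(sample, "paired_sample"))
  if (is.null(gate)) {
    gx <- as.character(suppressWarnings(normality_gate(sample$x, alpha)))
    gy <- as.character(suppressWarnings(normality_gate(sample$y, alpha)))
    gate <- if (gx == "normal" && gy == "normal") "normal" else "non_normal"
  }
  gate <- match.arg(gate, c("normal", "non_normal"))
  if (gate == "non_normal" && (sd(sample$x) == 0 || sd(sample$y) == 0))
    stop("tie-only vector: Spearman correlation undefined")
  type <- if (gate == "normal") "pearson" else "spearman"
  r <- cor(sample$x, sample$y, method = type)
  list(coefficient = r, type = type, band = correlation_band(r))
}

#' @rdname correlation
#' @param r correlation coefficient.
#' @export
correlation_band <- function(r) {
  vapply(r, function(v) {
    if (is.na(v)) NA_character_
    else if (v > 0.7) "very strong"
    else if (v >= 0.4) "strong"
    else if (v >= 0.3) "moderate"
    else if (v >= 0.2) "weak"
    else "none"
  }, character(1))
}

#' Two-way single-measure intraclass correlation
#'
#' Two-way model, single measurement, in the McGraw-Wong parameterisation:
#' `mode = "consistency"` gives ICC(C,1) (between-method variance excluded
#' from the error term) and `mode = "absolute"` gives ICC(A,1) (included).
#' The between-method variance component in the absolute denominator is the
#' non-negative variance-component estimate `max(MSC - MSE, 0)/n * k`, so
#' ICC(A,1) <= ICC(C,1) holds for every sample (the raw mean-square
#' difference can go negative by sampling noise even though the component
#' it estimates cannot). Confidence intervals use the standard
#' F-distribution constructions (Satterthwaite degrees of freedom for the
#' absolute form). Negative estimates are returned as computed.
#'
#' @param sample a [paired_sample()].
#' @param mode `"absolute"` or `"consistency"`.
#' @param conf confidence level, default 0.95.
#' @return List with `icc`, `ci95 = c(lower, upper)` and `mode`.
#' @export
icc <- function(sample, mode = c("absolute", "consistency"), conf = 0.95) {
  stopifnot(inherits(sample, "paired_sample"))
  mode <- match.arg(mode)
  n <- sample$n; k <- 2
  if (n < 5) stop("need at least 5 pairs for a meaningful ICC")
  m <- cbind(sample$x, sample$y)
  if (var(as.vector(m)) == 0) stop("zero total variance: ICC undefined")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  a2 <- 1 - (1 - conf) / 2
  if (mode == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) return(list(icc = 1, ci95 = c(1, 1), mode = mode))
    fobs <- msr / mse
    fl <- fobs / qf(a2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * qf(a2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * max(msc - mse, 0))
    if (mse == 0 && msc == 0) return(list(icc = 1, ci95 = c(1, 1), mode = mode))
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(a2, n - 1, v)
    fu <- qf(a2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  list(icc = est, ci95 = ci, mode = mode)
}

#' Verbal agreement band for an ICC
#'
#' Bands: <= 0 poor; 0.01-0.20 slight; 0.21-0.40 fair; 0.41-0.60 moderate;
#' 0.61-0.80 substantial; 0.81-1.00 almost perfect.
#'
#' @param value ICC estimate.
#' @return Character band label.
#' @export
#' @examples
#' icc_band(c(0.86, 0.5, -0.27))
icc_band <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) NA_character_
    else if (v <= 0) "poor"
    else if (v <= 0.20) "slight"
    else if (v <= 0.40) "fair"
    else if (v <= 0.60) "moderate"
    else if (v <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Technical error of measurement for duplicate readings
#'
#' `TEM = sqrt(sum(d^2) / (2n))` over n duplicate pairs; the relative TEM
#' expresses it as a percentage of the grand mean of all readings.
#'
#' @param first,second numeric vectors of first and second readings.
#' @return List with `tem_abs`, `tem_relative_percent` and `grand_mean`.
#' @export
#' @examples
#' tem(c(10, 20, 30), c(10.2, 19.8, 30.4))
tem <- function(first, second) {
  if (length(first) != length(second)) stop("readings must be paired")
  keep <- complete.cases(first, second)
  first <- first[keep]; second <- second[keep]
  if (length(first) < 2) stop("need at least 2 duplicate pairs")
  d <- first - second
  tem_abs <- sqrt(sum(d^2) / (2 * length(d)))
  gm <- mean(c(first, second))
  if (gm == 0) stop("zero grand mean: relative TEM undefined")
  list(tem_abs = tem_abs, tem_relative_percent = tem_abs / gm * 100,
       grand_mean = gm)
}

#' Fisher z confidence interval for a correlation-type coefficient
#'
#' `z = atanh(icc) +/- z_(1-alpha/2)/sqrt(n - 3)`, back-transformed with
#' `tanh`. Used for inter-rater ICC reporting.
#'
#' @param icc coefficient in (-1, 1); at |icc| = 1 the interval degenerates
#'   with a warning.
#' @param n number of paired observations, >= 4.
#' @param conf confidence level, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
fisher_z_icc_ci <- function(icc, n, conf = 0.95) {
  if (n < 4) stop("need n >= 4")
  if (abs(icc) > 1) stop("coefficient outside [-1, 1]")
  if (abs(icc) == 1) {
    warning("|coefficient| = 1: degenerate interval")
    return(c(icc, icc))
  }
  z <- atanh(icc)
  hw <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Sample size for a paired mean-difference design
#'
#' Two-sided normal approximation:
#' `n = ceil(((z_(1-alpha/2) + z_power) * sd_diff / delta)^2)`, clamped to a
#' minimum of 2.
#'
#' @param delta expected mean difference (same unit as `sd_diff`), > 0.
#' @param sd_diff standard deviation of the paired differences, > 0.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return Integer sample size.
#' @export
#' @examples
#' paired_sample_size(1, 1.8, 0.05, 0.8)  # 26
paired_sample_size <- function(delta, sd_diff, alpha = 0.05, power = 0.8) {
  if (delta <= 0) stop("delta must be positive")
  if (sd_diff <= 0) stop("sd_diff must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  n <- ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) * sd_diff / delta)^2)
  max(n, 2L)
}

#' Full agreement report for one equation
#'
#' Assembles the whole battery into a one-row data.frame matching the
#' method-comparison report schema: bias (reference - estimate) with SED and
#' CI, normality-gated paired test with Bonferroni flag, both ICC modes with
#' CIs and bands, correlation with band, RMA slope/intercept and
#' Bland-Altman limits of agreement.
#'
#' @param sample a [paired_sample()].
#' @param m Bonferroni family size (number of comparisons).
#' @param alpha family-wise significance level.
#' @return One-row data.frame.
#' @export
agreement_report <- function(sample, m = 1, alpha = 0.05) {
  stopifnot(inherits(sample, "paired_sample"))
  bs <- bias_stats(sample)
  tst <- paired_test(sample, alpha = alpha)
  ia <- icc(sample, "absolute")
  ic <- icc(sample, "consistency")
  gate <- if (!is.na(tst$gate_x) && tst$gate_x == "normal" &&
                tst$gate_y == "normal") "normal" else "non_normal"
  cr <- correlation(sample, gate = gate)
  rma <- rma_regression(sample)
  ba <- bland_altman(sample)
  thr <- bonferroni_threshold(alpha, m)
  data.frame(
    equation_id = if (is.null(sample$equation_id)) NA_character_ else sample$equation_id,
    family = if (is.null(sample$family)) NA_character_ else sample$family,
    n = sample$n,
    mean_est = mean(sample$x), sd_est = sd(sample$x),
    mean_ref = mean(sample$y), sd_ref = sd(sample$y),
    mean_diff = bs$mean_diff, sd_diff = bs$sd_diff, sed = bs$sed,
    ci_lower = bs$ci95[1], ci_upper = bs$ci95[2],
    p_value = tst$p_value, test_used = tst$test_used,
    gate_x = tst$gate_x, gate_y = tst$gate_y,
    bonferroni_alpha = thr,
    significant_after_bonferroni = tst$p_value < thr,
    icc_absolute = ia$icc, icc_abs_lower = ia$ci95[1], icc_abs_upper = ia$ci95[2],
    icc_abs_band = icc_band(ia$icc),
    icc_consistency = ic$icc, icc_con_lower = ic$ci95[1], icc_con_upper = ic$ci95[2],
    icc_con_band = icc_band(ic$icc),
    corr = cr$coefficient, corr_type = cr$type, corr_band = cr$band,
    rma_slope = rma$slope, rma_intercept = rma$intercept,
    loa_lower = ba$loa[1], loa_upper = ba$loa[2],
    stringsAsFactors = FALSE)
}
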