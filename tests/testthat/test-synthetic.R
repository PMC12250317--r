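test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(a, c2))
})

test_that("sample moments converge to the configured targets", {
  cfg <- cohort_config(n_subjects = 10000,
                       amputation_mix = c(transtibial = 10000),
                       seed = 2024)
  co <- generate_cohort(cfg)
  tm <- table2_moments()
  for (var in c("sk_tr", "sk_ab", "circ_waist", "height_cm", "body_weight_kg")) {
    target <- tm[tm$variable == var, ]
    se <- target$sd / sqrt(nrow(co))
    expect_lt(abs(mean(co[[var]]) - target$mean), 3 * se, label = var)
    expect_lt(abs(sd(co[[var]]) / target$sd - 1), 0.05, label = var)
  }
  # sex structure: women carry thicker triceps folds, narrower waists
  expect_gt(mean(co$sk_tr[co$sex == "female"]),
            mean(co$sk_tr[co$sex == "male"]))
  expect_lt(mean(co$circ_waist[co$sex == "female"]),
            mean(co$circ_waist[co$sex == "male"]))
  # latent adiposity induces positive fold-fold and fold-girth correlation
  expect_gt(cor(co$sk_tr, co$sk_ab), 0.3)
  expect_gt(cor(co$sk_ab, co$circ_waist), 0.2)
})

test_that("the moment-matched 27-subject cohort hits the targets exactly", {
  co <- fixture_table2_cohort(seed = 1)
  expect_equal(nrow(co), 27)
  expect_equal(sum(co$sex == "male"), 22)
  expect_equal(mean(co$circ_waist), 95)
  expect_equal(sd(co$dexa_fp), 6.83)
  expect_equal(mean(co$dexa_fp), 27.1)
  expect_equal(mean(co$sk_tr), 11.8)
  expect_equal(sd(co$sk_ss), 8.3)
  expect_equal(mean(co$bmi), 24.6)
  expect_equal(attr(co$bmi, "provenance"), "given")
  expect_equal(as.vector(table(co$amputation_level)[c(
    "transtibial", "transfemoral", "hip_disarticulation")]), c(15, 9, 3))
  expect_identical(co, fixture_table2_cohort(seed = 1))
  expect_silent(validate_cohort(co, require_references = TRUE))
})

test_that("reference model injects the configured bias and noise", {
  cfg <- cohort_config(seed = 55,
                       reference_model = list(family = "FP",
                                              equation_id = "hastuti",
                                              bias = 0, noise_sd = 0))
  co <- generate_cohort(cfg)
  expect_equal(co$dexa_fp, estimate_fp("hastuti", co), tolerance = 1e-12)
  # reference variables close on body weight
  expect_equal(co$dexa_fm, co$dexa_fp * co$body_weight_kg / 100)
  expect_equal(co$dexa_lm + co$dexa_fm + co$dexa_bmc, co$body_weight_kg)
  expect_equal(co$dexa_lp, co$dexa_lm / co$body_weight_kg * 100)
})

test_that("duplicate-measurement fixture recovers the target relative TEM", {
  v <- rep(c(10, 20, 30, 40), 50)
  same <- duplicate_measurement_fixture(v, rel_tem_percent = 0, seed = 1)
  expect_identical(same$first, same$second)
  set.seed(99)
  big <- duplicate_measurement_fixture(rnorm(20000, 25, 3), 0.7, seed = 99)
  r <- tem(big$first, big$second)
  expect_lt(abs(r$tem_relative_percent - 0.7), 0.02)
  # recovery tightens with n
  errs <- vapply(c(200, 20000), function(n) {
    dd <- duplicate_measurement_fixture(rep(25, n), 0.7, seed = n)
    abs(tem(dd$first, dd$second)$tem_relative_percent - 0.7)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})
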