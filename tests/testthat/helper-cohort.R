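# Small in-code fixtures shared across test files.

# One male subject at the published cohort means (all sites present).
mean_male_profile <- function() {
  data.frame(
    subject_id = "mean", sex = "male", age = 32.85, race = "hispanic",
    body_weight_kg = 69.52, height_cm = 167.63,
    sk_bi = 7, sk_tr = 11.8, sk_ss = 18.3, sk_si = 23.07, sk_ssp = 15.31,
    sk_ab = 25.45, sk_th = 14.4, sk_c = 9.77,
    circ_arm = 32.05, circ_forearm = 26, circ_thigh = 55.59,
    circ_calf = 36.76, circ_chest = 100, circ_waist = 95, circ_hip = 98,
    diam_wrist = 5.5, diam_femur = 9.4,
    amputation_level = "transtibial", measured_side = "intact",
    stringsAsFactors = FALSE)
}

# Random single-sex cohort with every measurement present (and a given bmi
# column so BMI-based equations are affine in the columns).
random_cohort <- function(n = 12, sex = "male", seed = 42) {
  set.seed(seed)
  base <- mean_male_profile()
  d <- base[rep(1, n), ]
  d$subject_id <- sprintf("r%02d", seq_len(n))
  d$sex <- sex
  num <- vapply(d, is.numeric, logical(1))
  for (col in names(d)[num]) {
    d[[col]] <- d[[col]] * exp(rnorm(n, 0, 0.08))
  }
  d$age <- pmax(d$age, 18)
  d$bmi <- compute_bmi(d$body_weight_kg, d$height_cm)
  rownames(d) <- NULL
  d
}
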