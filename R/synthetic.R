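# Synthetic cohorts ----------------------------------------------------------
#
# The generator emulates a small mixed-sex para-athlete cohort: skinfolds
# are log-normal with a shared latent adiposity factor, girths and frame
# measures are normal with loadings on a frame factor and on adiposity, sex
# shifts site means (contrasts centred so pooled moments stay on target),
# and the reference (DXA-style) variable for the family under study is
# simulated as equation(profile) + bias + noise, the remaining reference
# variables being filled in consistently (FM = FP*BW/100, LM = BW - FM -
# BMC, LP = LM/BW*100).

#' Per-variable moment targets of the emulated study sample
#'
#' Published sample means and SDs (n = 27 mixed-sex para-athletes) for age,
#' weight, height, BMI, DXA outcomes, five girths and eight skinfolds. Four
#' variables the descriptive table does not report — forearm and hip girths
#' and the wrist/femur breadths — carry synthetic defaults (flagged in the
#' `synthetic` column) chosen as typical adult values.
#'
#' @return data.frame with columns `variable`, `mean`, `sd`, `synthetic`.
#' @export
table2_moments <- function() {
  d <- read.csv(text = "variable,mean,sd,synthetic
age,32.85,7.38,FALSE
body_weight_kg,69.52,13.39,FALSE
height_cm,167.63,6.8,FALSE
bmi,24.6,3.68,FALSE
dexa_fp,27.1,6.83,FALSE
dexa_fm,18.32,6.1,FALSE
dexa_lp,50.66,9.24,FALSE
dexa_lm,49.16,9.53,FALSE
dexa_bmc,2.5,0.42,FALSE
circ_arm,32.05,4.54,FALSE
circ_thigh,55.59,4.88,FALSE
circ_calf,36.76,3.4,FALSE
circ_chest,100,8.6,FALSE
circ_waist,95,7.11,FALSE
sk_tr,11.8,5.07,FALSE
sk_ss,18.3,8.3,FALSE
sk_bi,7,3.6,FALSE
sk_si,23.07,8.07,FALSE
sk_ssp,15.31,7.86,FALSE
sk_ab,25.45,9.02,FALSE
sk_th,14.4,6,FALSE
sk_c,9.77,5.26,FALSE
circ_forearm,26,2.5,TRUE
circ_hip,98,6,TRUE
diam_wrist,5.5,0.35,TRUE
diam_femur,9.4,0.6,TRUE", stringsAsFactors = FALSE)
  d
}

# Female-minus-male contrasts. Skinfold contrasts are on the log scale
# (women carry relatively thicker peripheral folds); girth/frame contrasts
# are additive in cm/kg. Centred at generation time so pooled moments match
# the targets.
.default_sex_contrasts <- function() {
  list(log_skinfold = c(sk_tr = 0.25, sk_th = 0.30, sk_bi = 0.20, sk_c = 0.15,
                        sk_ss = 0, sk_si = 0, sk_ssp = 0, sk_ab = 0),
       additive = c(circ_arm = -3, circ_forearm = -2.5, circ_thigh = 0,
                    circ_calf = -2, circ_chest = -8, circ_waist = -6,
                    circ_hip = 4, height_cm = -11, body_weight_kg = -12,
                    diam_wrist = -0.6, diam_femur = -0.7, dexa_bmc = -0.4))
}

#' Configuration of a synthetic cohort
#'
#' @param n_subjects cohort size (default 27).
#' @param male_fraction fraction of male subjects (default 22/27).
#' @param amputation_mix named counts over amputation levels; scaled to
#'   `n_subjects` when they do not already sum to it.
#' @param target_moments data.frame as returned by [table2_moments()].
#' @param adiposity_share,frame_share shares of each variable's variance
#'   carried by the latent adiposity and frame factors (skinfolds load only
#'   on adiposity, on the log scale; girths on both).
#' @param sex_contrasts list with elements `log_skinfold` and `additive`;
#'   see `anthroagree:::.default_sex_contrasts`.
#' @param reference_model list with `family` (`"FP"`, `"FM"`, `"LP"`,
#'   `"LM"`), `equation_id`, `bias` and `noise_sd`: the reference value for
#'   that family is simulated as equation + bias + N(0, noise_sd^2).
#' @param race race category assigned to every subject (the source study
#'   does not report a race mix).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 27,
                          male_fraction = 22 / 27,
                          amputation_mix = c(transtibial = 15, transfemoral = 9,
                                             hip_disarticulation = 3),
                          target_moments = table2_moments(),
                          adiposity_share = 0.5,
                          frame_share = 0.3,
                          sex_contrasts = .default_sex_contrasts(),
                          reference_model = list(family = "FP",
                                                 equation_id = "hastuti",
                                                 bias = 0.7, noise_sd = 4.55),
                          race = "hispanic",
                          seed = NULL) {
  stopifnot(n_subjects >= 3, male_fraction >= 0, male_fraction <= 1,
            all(target_moments$sd > 0),
            adiposity_share >= 0, frame_share >= 0,
            adiposity_share + frame_share <= 1)
  if (any(target_moments$mean <= 0))
    stop("infeasible moments: negative or zero implied values")
  reference_model$family <- match.arg(reference_model$family,
                                      c("FP", "FM", "LP", "LM"))
  if (sum(amputation_mix) != n_subjects) {
    amputation_mix <- round(amputation_mix / sum(amputation_mix) * n_subjects)
    amputation_mix[1] <- n_subjects - sum(amputation_mix[-1])
  }
  structure(list(n_subjects = n_subjects, male_fraction = male_fraction,
                 amputation_mix = amputation_mix,
                 target_moments = target_moments,
                 adiposity_share = adiposity_share, frame_share = frame_share,
                 sex_contrasts = sex_contrasts,
                 reference_model = reference_model, race = race, seed = seed),
            class = "cohort_config")
}

.moment <- function(tm, var) {
  row <- tm[tm$variable == var, ]
  if (nrow(row) != 1) stop("no moment target for variable: ", var)
  c(mean = row$mean, sd = row$sd)
}

# Centred sex offsets: female - male contrast c, pooled expectation zero.
.centred_offsets <- function(contrast, male_fraction) {
  c(male = -(1 - male_fraction) * contrast, female = male_fraction * contrast)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the configuration seed. Sample moments converge to
#' the configured targets as n grows; see [fixture_table2_cohort()] for an
#' exactly moment-matched 27-subject cohort.
#'
#' @param config a [cohort_config()].
#' @param opts an [anthro_options()] list used when evaluating the reference
#'   model equation.
#' @return A validated cohort data.frame including reference columns.
#' @export
generate_cohort <- function(config = cohort_config(), opts = anthro_options()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  tm <- config$target_moments
  n_male <- round(config$male_fraction * n)
  sex <- rep(c("male", "female"), c(n_male, n - n_male))

  adip <- rnorm(n)
  frame <- rnorm(n)

  d <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                  sex = sex, race = config$race,
                  stringsAsFactors = FALSE)

  # age: independent, truncated at 18 by re-drawing
  am <- .moment(tm, "age")
  age <- am["mean"] + am["sd"] * rnorm(n)
  while (any(age < 18))
    age[age < 18] <- am["mean"] + am["sd"] * rnorm(sum(age < 18))
  d$age <- age

  a_sh <- config$adiposity_share
  f_sh <- config$frame_share
  # variance shares for the normal variables
  shares <- list(height_cm = c(0, 0.6), body_weight_kg = c(0.35, 0.45),
                 circ_arm = c(a_sh, f_sh), circ_forearm = c(a_sh, f_sh),
                 circ_thigh = c(a_sh, f_sh), circ_calf = c(a_sh, f_sh),
                 circ_chest = c(a_sh, f_sh), circ_waist = c(a_sh + 0.1, f_sh),
                 circ_hip = c(a_sh, f_sh),
                 diam_wrist = c(0, 0.5), diam_femur = c(0, 0.5),
                 dexa_bmc = c(0, 0.4))
  add_off <- config$sex_contrasts$additive
  mf <- config$male_fraction
  for (var in names(shares)) {
    mo <- .moment(tm, var)
    sh <- shares[[var]]
    resid <- sqrt(max(0, 1 - sh[1] - sh[2]))
    # the centred sex contrast contributes mf(1-mf)c^2 to the pooled
    # variance; shrink the stochastic part so the pooled SD stays on target
    vc <- if (var %in% names(add_off))
      mf * (1 - mf) * add_off[[var]]^2 else 0
    sd_eff <- sqrt(max(mo["sd"]^2 - vc, 1e-8))
    v <- mo["mean"] + sd_eff * (sqrt(sh[1]) * adip + sqrt(sh[2]) * frame +
                                  resid * rnorm(n))
    if (var %in% names(add_off)) {
      off <- .centred_offsets(add_off[[var]], mf)
      v <- v + ifelse(sex == "male", off["male"], off["female"])
    }
    d[[var]] <- as.numeric(v)
  }

  # skinfolds: log-normal with adiposity loading, sex contrast on log scale,
  # log-mean corrected so the pooled arithmetic mean stays on target
  log_off <- config$sex_contrasts$log_skinfold
  for (var in paste0("sk_", c("bi", "tr", "ss", "si", "ssp", "ab", "th", "c"))) {
    mo <- .moment(tm, var)
    cv2 <- (mo["sd"] / mo["mean"])^2
    sl2 <- log(1 + cv2)
    off <- c(male = 0, female = 0)
    vc <- 0
    if (var %in% names(log_off) && log_off[[var]] != 0) {
      off <- .centred_offsets(log_off[[var]], mf)
      vc <- mf * (1 - mf) * log_off[[var]]^2  # contrast share of the log-variance
    }
    sl2_eff <- max(sl2 - vc, 1e-8)
    lam <- sqrt(a_sh * sl2_eff)
    res <- sqrt(sl2_eff - lam^2)
    # log-mean chosen so the pooled arithmetic mean hits the target exactly
    mu <- log(mo["mean"]) - sl2_eff / 2 -
      log(mf * exp(off["male"]) + (1 - mf) * exp(off["female"]))
    lv <- mu + lam * adip + res * rnorm(n) +
      ifelse(sex == "male", off["male"], off["female"])
    d[[var]] <- as.numeric(exp(lv))
  }

  d$amputation_level <- rep(names(config$amputation_mix), config$amputation_mix)
  d$measured_side <- "intact"

  d <- .fill_references(d, config, opts)
  validate_cohort(d)
  d
}

# Simulate the reference variable of the family under study from the
# configured equation, then derive the remaining reference columns so that
# FP, FM, LM and BMC close on body weight.
.fill_references <- function(d, config, opts) {
  rm_ <- config$reference_model
  est <- estimate_composition(rm_$equation_id, d, opts)
  refv <- est + rm_$bias + rnorm(nrow(d), 0, rm_$noise_sd)
  bw <- d$body_weight_kg
  bmc <- d$dexa_bmc
  switch(rm_$family,
         FP = {
           d$dexa_fp <- pmin(pmax(refv, 1), 99)
           d$dexa_fm <- d$dexa_fp * bw / 100
           d$dexa_lm <- bw - d$dexa_fm - bmc
           d$dexa_lp <- d$dexa_lm / bw * 100
         },
         FM = {
           d$dexa_fm <- pmin(pmax(refv, 0.5), bw * 0.95)
           d$dexa_fp <- d$dexa_fm / bw * 100
           d$dexa_lm <- bw - d$dexa_fm - bmc
           d$dexa_lp <- d$dexa_lm / bw * 100
         },
         LM = {
           d$dexa_lm <- pmin(pmax(refv, 10), bw * 0.95)
           d$dexa_lp <- d$dexa_lm / bw * 100
           d$dexa_fm <- pmax(bw - d$dexa_lm - bmc, 0.5)
           d$dexa_fp <- d$dexa_fm / bw * 100
         },
         LP = {
           d$dexa_lp <- pmin(pmax(refv, 1), 99)
           d$dexa_lm <- d$dexa_lp * bw / 100
           d$dexa_fm <- pmax(bw - d$dexa_lm - bmc, 0.5)
           d$dexa_fp <- d$dexa_fm / bw * 100
         })
  d
}

#' Exactly moment-matched 27-subject cohort
#'
#' Generates a default cohort and then rescales every targeted variable
#' affinely so its sample mean and SD equal the published descriptive
#' moments exactly (including the descriptive-table BMI, which is attached
#' as a `bmi` column with provenance "given"), approximately preserving the
#' configured correlation structure. Draws are repeated with derived
#' sub-seeds until the standardised cohort satisfies the positivity and
#' adult-age invariants.
#'
#' @param seed integer seed.
#' @param config a [cohort_config()]; `n_subjects` must match the moment
#'   table's design (27) for the published targets.
#' @return A validated cohort data.frame whose per-variable sample moments
#'   match the targets to float precision.
#' @export
fixture_table2_cohort <- function(seed = 1, config = cohort_config()) {
  tm <- config$target_moments
  for (try in 0:199) {
    config$seed <- seed + 10000L * try
    d <- generate_cohort(config)
    d$bmi <- compute_bmi(d$body_weight_kg, d$height_cm)
    for (var in tm$variable) {
      mo <- .moment(tm, var)
      v <- d[[var]]
      d[[var]] <- mo["mean"] + (v - mean(v)) * mo["sd"] / sd(v)
    }
    ok <- tryCatch({ validate_cohort(d, require_references = TRUE); TRUE },
                   error = function(e) FALSE)
    if (ok) {
      attr(d$bmi, "provenance") <- "given"
      return(d)
    }
  }
  stop("could not generate a valid moment-matched cohort in 200 attempts")
}

#' Duplicate-measurement fixture for TEM recovery
#'
#' Produces a second reading for each value with independent error scaled so
#' the expected relative technical error of measurement equals
#' `rel_tem_percent`: the error SD is `rel_tem/100 * grand mean * sqrt(2)`,
#' since `E[TEM^2] = sd^2 / 2` for differences with that SD.
#'
#' @param values numeric vector of first readings.
#' @param rel_tem_percent target relative TEM, in percent (>= 0).
#' @param seed integer seed, or `NULL`.
#' @return data.frame with columns `first` and `second`.
#' @export
duplicate_measurement_fixture <- function(values, rel_tem_percent = 0.7, seed = NULL) {
  if (rel_tem_percent < 0) stop("rel_tem_percent must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sd_err <- rel_tem_percent / 100 * mean(values) * sqrt(2)
  data.frame(first = values,
             second = values + rnorm(length(values), 0, sd_err))
}
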