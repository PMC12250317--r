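test_that("body-density equations reproduce hand-evaluated values", {
  d <- mean_male_profile()
  # Durnin-Womersley male at a round log: sum 100 -> 1.1765 - 2*0.0744
  d100 <- d
  d100[, c("sk_bi", "sk_tr", "sk_ss", "sk_si")] <- 25
  expect_equal(estimate_bd("durnin_womersley", d100), 1.0277)
  # at the cohort-mean folds (sum 60.17)
  expect_equal(estimate_bd("durnin_womersley", d),
               1.1765 - 0.0744 * log10(60.17), tolerance = 1e-12)
  expect_equal(round(estimate_bd("durnin_womersley", d), 5), 1.04411)
  # female intercept/slope differ
  df <- d; df$sex <- "female"
  expect_equal(estimate_bd("durnin_womersley", df),
               1.1567 - 0.0717 * log10(60.17), tolerance = 1e-12)
  # degenerate folds rejected where a log is involved
  d0 <- d
  d0[, c("sk_bi", "sk_tr", "sk_ss", "sk_si", "sk_ab", "sk_th", "sk_c")] <- 0
  expect_error(estimate_bd("withers", d0), "> 0")
})

test_that("Siri and Brozek converters sit on the percent scale", {
  expect_equal(bd_to_fp("siri", 1.1), 0)
  expect_equal(bd_to_fp("brozek", 1.1), 457 / 1.1 - 414.2)
  expect_equal(round(bd_to_fp("brozek", 1.1), 4), 1.2545)
  expect_equal(round(bd_to_fp("siri", 1.04411), 2), 24.09)
  # a typical density gives a plausible fat percentage
  expect_equal(round(bd_to_fp("siri", 1.05), 1), 21.4)
  expect_warning(bd_to_fp("siri", 0.85), "physiological")
})

test_that("Siri exceeds Brozek exactly below the analytic crossover", {
  # 495/BD - 450 = 457/BD - 414.2  =>  BD* = 38/35.8
  bd_star <- 38 / 35.8
  expect_equal(round(bd_star, 4), 1.0615)
  grid <- seq(0.95, 1.15, by = 1e-4)
  siri <- 100 * (4.95 / grid - 4.5)
  brozek <- 100 * (4.57 / grid - 4.142)
  flips <- which(diff(sign(siri - brozek)) != 0)
  expect_length(flips, 1)
  expect_lt(abs(grid[flips] - bd_star), 2e-4)
  expect_true(all(bd_to_fp("siri", grid[grid < bd_star - 1e-3]) >
                    bd_to_fp("brozek", grid[grid < bd_star - 1e-3])))
  # the crossover sits near 16.3% fat
  expect_equal(round(bd_to_fp("siri", bd_star), 1), 16.3)
})

test_that("direct fat-percentage equations match hand evaluation", {
  d <- mean_male_profile()
  expect_equal(estimate_fp("hastuti", d),
               17.026 + 0.509 * 11.8 + 0.342 * 23.07 - 5.594, tolerance = 1e-12)
  expect_equal(round(estimate_fp("hastuti", d), 2), 25.33)
  d0 <- d; d0$sk_tr <- 1e-300; d0$sk_si <- 1e-300
  expect_equal(estimate_fp("hastuti", d0), 17.026 - 5.594, tolerance = 1e-9)
  dfem <- d; dfem$sex <- "female"
  expect_equal(estimate_fp("hastuti", dfem) - estimate_fp("hastuti", d), 5.594)
  # composite BD + converter chains the two steps
  expect_equal(estimate_fp("durnin_womersley+siri", d),
               bd_to_fp("siri", estimate_bd("durnin_womersley", d)))
  expect_error(estimate_fp("durnin_womersley+nonsense", d), "composite")
})

test_that("fat-mass equations match hand evaluation and printed structure", {
  d <- mean_male_profile()
  # De Rose product form: BW = 100, zero folds -> 5.783 kg
  dz <- d; dz$body_weight_kg <- 100
  dz[, c("sk_ss", "sk_tr", "sk_ssp", "sk_ab")] <- 1e-300
  expect_equal(estimate_fm("de_rose_fm", dz), 5.783, tolerance = 1e-9)
  expect_equal(round(estimate_fm("de_rose_fm", d), 2), 11.56)
  # Kerr adipose mass: zero Z-score at reference stature gives the phantom mass
  dk <- d; dk$height_cm <- 170.18
  s6 <- 102.79
  dk[, c("sk_tr", "sk_ss", "sk_si", "sk_ab", "sk_th", "sk_c")] <-
    as.list(d[, c("sk_tr", "sk_ss", "sk_si", "sk_ab", "sk_th", "sk_c")] *
              (116.41 / s6))
  expect_equal(estimate_fm("isak5_fm", dk), 25.6, tolerance = 1e-9)
  # the literal printed form (no Z-score) is non-physical at cohort scale
  fm_lit <- estimate_fm("isak5_fm", d, anthro_options(as_printed = TRUE))
  expect_gt(fm_lit, 500)
})

test_that("lean-mass equations match hand evaluation", {
  d <- mean_male_profile()
  # Lee RC 2 with round inputs, height in metres
  d2 <- data.frame(subject_id = "x", sex = "male", age = 30, race = "white",
                   body_weight_kg = 70, height_cm = 170)
  expect_equal(estimate_lm("lee_rc_2", d2),
               0.244 * 70 + 7.8 * 1.70 + 6.6 - 0.098 * 30 - 3.3,
               tolerance = 1e-12)
  expect_equal(round(estimate_lm("lee_rc_2", d2), 2), 30.70)
  # race offsets as printed
  d2a <- d2; d2a$race <- "asian"
  expect_equal(estimate_lm("lee_rc_2", d2a) - estimate_lm("lee_rc_2", d2), -1.2)
  # Kerr muscle mass: ZMUS = 0 at reference stature gives the phantom mass
  dk <- d; dk$height_cm <- 170.18
  s5 <- corrected_girth(dk$circ_arm, dk$sk_tr) + dk$circ_forearm +
    corrected_girth(dk$circ_thigh, dk$sk_th) +
    corrected_girth(dk$circ_calf, dk$sk_c) +
    corrected_girth(dk$circ_chest, dk$sk_ss)
  dk$circ_forearm <- dk$circ_forearm + (207.21 - s5)
  expect_equal(estimate_lm("isak5_lm", dk), 24.5, tolerance = 1e-9)
  expect_equal(estimate_lp("isak5_lp", transform(dk, body_weight_kg = 49)),
               50, tolerance = 1e-9)
  # De Rose closure: FM + bone + residual + LM = BW for any valid profile
  co <- random_cohort(n = 8, seed = 11)
  fm <- estimate_fm("de_rose_fm", co)
  lm <- estimate_lm("de_rose_lm", co)
  hm <- co$height_cm / 100
  bm <- 3.02 * (hm^2 * (co$diam_wrist / 100) * (co$diam_femur / 100) * 400)^0.712
  expect_equal(fm + bm + 0.241 * co$body_weight_kg + lm, co$body_weight_kg,
               tolerance = 1e-12)
  expect_error(estimate_lm("de_rose_lm", transform(co, diam_wrist = NA)),
               "diam_wrist")
})

test_that("lean percentage is lean mass over body weight on the percent scale", {
  co <- random_cohort(n = 6, seed = 3)
  expect_equal(estimate_lp("lee_rc_lp", co),
               estimate_lm("lee_rc_1", co) / co$body_weight_kg * 100)
  expect_error(estimate_lp("lee_rc_lp", transform(co, body_weight_kg = NA)),
               "body_weight_kg")
})

test_that("registry counts match the comparison families", {
  expect_equal(nrow(list_equations("FP")), 34)
  expect_equal(nrow(list_equations("FM")), 6)
  expect_equal(nrow(list_equations("LP")), 3)
  expect_equal(nrow(list_equations("LM")), 13)
  expect_equal(nrow(list_equations("BD")), 8)
  # the amputee-specific skinfold models are registered but untested by default
  all_fp <- list_equations("FP", tested_only = FALSE)
  expect_equal(nrow(all_fp), 36)
  expect_true(all(c("cavedon1", "cavedon2") %in% all_fp$equation_id))
})

test_that("every registered equation's inputs exist in the cohort schema", {
  reg <- equation_registry()
  cols <- cohort_columns()
  for (i in seq_len(nrow(reg))) {
    needs <- strsplit(reg$required_inputs[i], ";")[[1]]
    expect_true(all(needs %in% cols), label = reg$equation_id[i])
  }
})

test_that("every tested equation evaluates on a complete profile", {
  co <- random_cohort(n = 5, seed = 9)
  co$race <- "hispanic"
  reg <- list_equations()
  for (id in reg$equation_id) {
    v <- estimate_composition(id, co)
    expect_true(all(is.finite(v)), label = id)
    expect_length(v, 5)
  }
})

test_that("affine equations commute with cohort averaging", {
  co <- random_cohort(n = 15, seed = 21)
  mean_row <- co[1, ]
  for (col in names(co)[vapply(co, is.numeric, logical(1))])
    mean_row[[col]] <- mean(co[[col]])
  affine <- c("hastuti", "deurenberg", "minematsu", "salamat_fm", "salamat_lm",
              "eston", "evans", "giro", "chien", "lee_rc_2", "lee_dh_fm",
              "lee_dh_fp", "lee_dh_lm", "faulkner", "yuhasz", "carter",
              "heitmann", "al_guindan", "olshvang", "lean_wc", "lean_bmi",
              "lean_bmi_tr", "de_rose_fm")
  # de_rose_fm is bilinear in (BW, folds); keep BW fixed to make it affine
  co2 <- co; co2$body_weight_kg <- 70; mr2 <- mean_row; mr2$body_weight_kg <- 70
  for (id in affine) {
    use <- if (id == "de_rose_fm") list(co2, mr2) else list(co, mean_row)
    expect_equal(mean(estimate_composition(id, use[[1]])),
                 estimate_composition(id, use[[2]]),
                 tolerance = 1e-9, label = id)
  }
})

test_that("fat estimates are non-decreasing and densities non-increasing in each fold", {
  base <- mean_male_profile()
  reg <- list_equations(tested_only = FALSE)
  fams <- reg[reg$output %in% c("FP", "FM", "BD"), ]
  fams <- fams[!grepl("+", fams$equation_id, fixed = TRUE), ]
  for (i in seq_len(nrow(fams))) {
    id <- fams$equation_id[i]
    needs <- strsplit(fams$required_inputs[i], ";")[[1]]
    sks <- grep("^sk_", needs, value = TRUE)
    prof <- base
    prof$sk_ax <- 12; prof$sk_ch <- 14  # optional sites for the Cavedon models
    v0 <- estimate_composition(id, prof)
    for (sk in sks) {
      bump <- prof
      bump[[sk]] <- bump[[sk]] + 1
      v1 <- estimate_composition(id, bump)
      if (fams$output[i] == "BD") {
        expect_lte(v1, v0)
      } else {
        expect_gte(v1, v0)
      }
    }
  }
})

test_that("sex-specific equations refuse profiles without an explicit sex", {
  d <- mean_male_profile()
  d$sex <- NA_character_
  expect_error(estimate_fp("hastuti", d), "sex")
})

test_that("evaluation options switch the documented variants", {
  d <- mean_male_profile()
  # O'Connor printed linear pair vs quadratic variant
  s <- 11.8 + 23.07 + 14.4
  expect_equal(estimate_fp("oconnor", d), 0.272 * s - 0.0005 * s + 4.972,
               tolerance = 1e-12)
  expect_equal(estimate_fp("oconnor", d, anthro_options(oconnor_squared = TRUE)),
               0.272 * s - 0.0005 * s^2 + 4.972, tolerance = 1e-12)
  # Heymsfield printed vs published height coefficient
  h_printed <- estimate_lm("heymsfield", d)
  h_pub <- estimate_lm("heymsfield", d,
                       anthro_options(heymsfield_coefficient = 0.0264))
  expect_equal(h_printed - h_pub, 167.63 * (0.284 - 0.0264), tolerance = 1e-9)
  # Doupe literal printed coefficients are a factor of ten off
  d_def <- estimate_lm("doupe", d)
  d_lit <- estimate_lm("doupe", d, anthro_options(as_printed = TRUE))
  expect_equal(d_lit + 3.006, (d_def + 3.006) * 10, tolerance = 1e-9)
})
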