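# Equation compendium --------------------------------------------------------
#
# Every estimator is vectorised over the cohort rows and pulls its inputs
# through .need()/.sk()/.cg() so a missing measurement produces an error
# naming both the site and the equation. Sex and race are stored on the
# profile as categories; each equation applies its own numeric coding here,
# at evaluation time. Heights: most equations take cm; the Lee RC, Doupe and
# Poortmans limb-girth models and the De Rose bone-mass term take metres and
# convert internally.

.sk <- function(d, site, id) .need(d, paste0("sk_", site), id)

.sexnum <- function(d, male, female, id) {
  if (!"sex" %in% names(d) || anyNA(d$sex))
    stop("equation '", id, "' is sex-specific: every subject needs an explicit sex")
  ifelse(d$sex == "male", male, female)
}

# Additive race offset. `map` holds the printed offsets; categories without a
# printed offset fall back to `map[["other"]]` when present, else to
# `fallback` (the printed baseline) or an error.
.racenum <- function(d, map, id, fallback = NULL) {
  if (!"race" %in% names(d) || anyNA(d$race))
    stop("equation '", id, "' requires a race category for every subject")
  out <- unname(map[d$race])
  if (anyNA(out)) {
    repl <- if ("other" %in% names(map)) map[["other"]] else fallback
    if (is.null(repl))
      stop("equation '", id, "' has no race coding for: ",
           paste(unique(d$race[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- repl
  }
  out
}

.sex_split <- function(d, male_fn, female_fn) {
  m <- d$sex == "male"
  out <- numeric(nrow(d))
  if (any(m)) out[m] <- male_fn(d[m, , drop = FALSE])
  if (any(!m)) out[!m] <- female_fn(d[!m, , drop = FALSE])
  out
}

.kerr_scale <- function(h_cm) (170.18 / h_cm)^3

# Body density ---------------------------------------------------------------

.bd_fns <- list(
  durnin_womersley = function(d, o) {
    s <- sum_skinfolds(d, c("bi", "tr", "ss", "si"), "durnin_womersley")
    if (any(s <= 0)) stop("skinfold sum must be > 0 (log10 undefined)")
    .sexnum(d, 1, 0, "durnin_womersley") * (1.1765 - 0.0744 * log10(s)) +
      .sexnum(d, 0, 1, "durnin_womersley") * (1.1567 - 0.0717 * log10(s))
  },
  forsyth_sinning = function(d, o)
    1.1103 - 0.00168 * .sk(d, "ss", "forsyth_sinning") -
      0.00127 * .sk(d, "ab", "forsyth_sinning"),
  katch_mcardle = function(d, o)
    1.09665 - 0.00103 * .sk(d, "tr", "katch_mcardle") -
      0.00056 * .sk(d, "ss", "katch_mcardle") -
      0.00054 * .sk(d, "ab", "katch_mcardle"),
  nagamine_suzuki = function(d, o)
    1.0913 - 0.00116 * (.sk(d, "tr", "nagamine_suzuki") + .sk(d, "ss", "nagamine_suzuki")),
  sloan = function(d, o)
    1.1043 - 0.001327 * .sk(d, "th", "sloan") - 0.00131 * .sk(d, "ss", "sloan"),
  wilmore_behnke = function(d, o)
    1.08543 - 0.000886 * .sk(d, "ab", "wilmore_behnke") - 0.0004 * .sk(d, "th", "wilmore_behnke"),
  withers = function(d, o) {
    s <- sum_skinfolds(d, c("tr", "ss", "bi", "si", "ab", "th", "c"), "withers")
    if (any(s <= 0)) stop("skinfold sum must be > 0")
    1.0988 - 0.0004 * s
  },
  white = function(d, o)
    1.0958 - 0.00088 * .sk(d, "si", "white") - 0.0006 * .sk(d, "th", "white")
)

#' Estimate body density
#'
#' Evaluates one of the eight skinfold-based body-density equations
#' (Durnin-Womersley, Forsyth-Sinning, Katch-McArdle, Nagamine-Suzuki,
#' Sloan, Wilmore-Behnke, Withers, White).
#'
#' @param equation_id one of `names(anthroagree:::.bd_fns)`, e.g.
#'   `"durnin_womersley"`.
#' @param cohort cohort data.frame.
#' @param opts an [anthro_options()] list.
#' @return Numeric vector of densities (g/ml-style, dimensionless here).
#' @export
#' @examples
#' d <- data.frame(subject_id = "a", sex = "male", age = 30,
#'                 body_weight_kg = 70, height_cm = 170,
#'                 sk_bi = 25, sk_tr = 25, sk_ss = 25, sk_si = 25)
#' estimate_bd("durnin_womersley", d)
estimate_bd <- function(equation_id, cohort, opts = anthro_options()) {
  fn <- .bd_fns[[match.arg(equation_id, names(.bd_fns))]]
  as.numeric(fn(cohort, opts))
}

#' Convert body density to fat percentage
#'
#' Two-compartment converters: Siri `FP = 100 * (4.95/BD - 4.5)` and Brozek
#' `FP = 100 * (4.57/BD - 4.142)`, both on the 0-100 percent scale (a BD of
#' about 1.05 maps to roughly 21% fat).
#'
#' @param converter `"siri"` or `"brozek"`.
#' @param bd body density.
#' @return Fat percentage.
#' @export
#' @examples
#' bd_to_fp("siri", 1.05)
bd_to_fp <- function(converter = c("siri", "brozek"), bd) {
  converter <- match.arg(converter)
  if (any(bd <= 0)) stop("body density must be positive")
  if (any(bd <= 0.9 | bd >= 1.2))
    warning("body density outside the physiological range (0.9, 1.2)")
  switch(converter,
         siri = 100 * (4.95 / bd - 4.5),
         brozek = 100 * (4.57 / bd - 4.142))
}

# Fat percentage -------------------------------------------------------------

.fp_fns <- list(
  eston = function(d, o)
    0.12 * sum_skinfolds(d, c("bi", "tr", "ss", "si"), "eston") +
      0.36 * (.sk(d, "th", "eston") + .sk(d, "c", "eston")) + 1.61,
  evans = function(d, o)
    8.997 + 0.24658 * (.sk(d, "ab", "evans") + .sk(d, "th", "evans") + .sk(d, "tr", "evans")) -
      6.343 * .sexnum(d, 1, 0, "evans") -
      1.998 * .racenum(d, c(afro_descendant = 1, white = 0), "evans", fallback = 0),
  oconnor = function(d, o) {
    s <- .sk(d, "tr", "oconnor") + .sk(d, "si", "oconnor") + .sk(d, "th", "oconnor")
    second <- if (isTRUE(o$oconnor_squared)) 0.0005 * s^2 else 0.0005 * s
    0.272 * s - second + 4.972
  },
  carter = function(d, o) {
    s6 <- sum_skinfolds(d, c("tr", "bi", "si", "ss", "th", "c"), "carter")
    .sexnum(d, 1, 0, "carter") * (2.585 + 0.1051 * s6) +
      .sexnum(d, 0, 1, "carter") * (3.5803 + 0.1548 * s6)
  },
  faulkner = function(d, o) {
    s4 <- sum_skinfolds(d, c("tr", "ss", "si", "ab"), "faulkner")
    .sexnum(d, 1, 0, "faulkner") * (s4 * 0.153 + 5.783) +
      .sexnum(d, 0, 1, "faulkner") * (s4 * 0.213 + 7.9)
  },
  slaughter = function(d, o) {
    ts <- .sk(d, "tr", "slaughter") + .sk(d, "ss", "slaughter")
    .sexnum(d, 1, 0, "slaughter") * (1.21 * ts - 0.008 * ts^2 - 3.4) +
      .sexnum(d, 0, 1, "slaughter") * (1.33 * ts - 0.013 * ts^2 - 2.5)
  },
  yuhasz = function(d, o) {
    s6 <- sum_skinfolds(d, c("tr", "ss", "si", "ab", "th", "c"), "yuhasz")
    .sexnum(d, 1, 0, "yuhasz") * (0.1051 * s6 + 2.58) +
      .sexnum(d, 0, 1, "yuhasz") * (0.1548 * s6 + 3.58)
  },
  minematsu = function(d, o)
    10.558 * .sexnum(d, 1, 2, "minematsu") + 0.069 * .need(d, "age", "minematsu") +
      0.667 * .cohort_bmi(d) + 0.314 * .need(d, "circ_waist", "minematsu") - 35.881,
  hastuti = function(d, o)
    17.026 + 0.509 * .sk(d, "tr", "hastuti") + 0.342 * .sk(d, "si", "hastuti") -
      5.594 * .sexnum(d, 1, 0, "hastuti"),
  deurenberg = function(d, o)
    1.2 * .cohort_bmi(d) + 0.23 * .need(d, "age", "deurenberg") -
      10.8 * .sexnum(d, 1, 0, "deurenberg") - 5.4,
  lean_wc = function(d, o) .sex_split(
    d,
    function(m) 0.567 * .need(m, "circ_waist", "lean_wc") + 0.101 * .need(m, "age", "lean_wc") - 31.8,
    function(f) 0.439 * .need(f, "circ_waist", "lean_wc") + 0.221 * .need(f, "age", "lean_wc") - 9.4),
  lean_bmi = function(d, o) .sex_split(
    d,
    function(m) 1.33 * .cohort_bmi(m) + 0.236 * .need(m, "age", "lean_bmi") - 20.2,
    function(f) 1.21 * .cohort_bmi(f) + 0.262 * .need(f, "age", "lean_bmi") - 6.7),
  lean_bmi_tr = function(d, o) .sex_split(
    d,
    function(m) 0.742 * .cohort_bmi(m) + 0.950 * .sk(m, "tr", "lean_bmi_tr") +
      0.335 * .need(m, "age", "lean_bmi_tr") - 20,
    function(f) 0.730 * .cohort_bmi(f) + 0.548 * .sk(f, "tr", "lean_bmi_tr") +
      0.270 * .need(f, "age", "lean_bmi_tr") - 5.9),
  lean_log4sk = function(d, o) {
    s4 <- sum_skinfolds(d, c("bi", "tr", "ss", "si"), "lean_log4sk")
    if (any(s4 <= 0)) stop("skinfold sum must be > 0 (log10 undefined)")
    .sexnum(d, 1, 0, "lean_log4sk") *
      (30.69 * log10(s4) + 0.271 * .need(d, "age", "lean_log4sk") - 39.9) +
      .sexnum(d, 0, 1, "lean_log4sk") *
        (30.8 * log10(s4) + 0.274 * .need(d, "age", "lean_log4sk") - 31.7)
  },
  gomez_ambrosi = function(d, o) {
    bmi <- .cohort_bmi(d); age <- .need(d, "age", "gomez_ambrosi")
    sx <- .sexnum(d, 0, 1, "gomez_ambrosi")
    -44.988 + 0.503 * age + 10.689 * sx + 3.172 * bmi - 0.026 * bmi^2 +
      0.181 * bmi * sx - 0.02 * bmi * age - 0.005 * bmi^2 * sx +
      0.00021 * bmi^2 * age
  },
  isak5_fp = function(d, o)
    .fm_fns$isak5_fm(d, o) / .need(d, "body_weight_kg", "isak5_fp") * 100,
  lee_dh_fp = function(d, o) .sex_split(
    d,
    function(m) 2.80 + 0.03 * .need(m, "age", "lee_dh_fp") -
      0.04 * .need(m, "height_cm", "lee_dh_fp") - 0.08 * .need(m, "body_weight_kg", "lee_dh_fp") +
      0.35 * .need(m, "circ_waist", "lee_dh_fp") - 0.18 * .need(m, "circ_arm", "lee_dh_fp") +
      0.00 * .need(m, "circ_calf", "lee_dh_fp") + 0.04 * .need(m, "circ_thigh", "lee_dh_fp") +
      0.33 * .sk(m, "tr", "lee_dh_fp") + 0.08 * .sk(m, "ss", "lee_dh_fp") +
      .racenum(m, c(mexican = 0.53, hispanic = 0.19, afro_descendant = -0.79, other = 0.7),
               "lee_dh_fp"),
    function(f) 32.75 + 0.08 * .need(f, "age", "lee_dh_fp") -
      0.16 * .need(f, "height_cm", "lee_dh_fp") + 0.10 * .need(f, "body_weight_kg", "lee_dh_fp") +
      0.12 * .need(f, "circ_waist", "lee_dh_fp") - 0.05 * .need(f, "circ_arm", "lee_dh_fp") -
      0.17 * .need(f, "circ_calf", "lee_dh_fp") + 0.22 * .need(f, "circ_thigh", "lee_dh_fp") +
      0.27 * .sk(f, "tr", "lee_dh_fp") + 0.05 * .sk(f, "ss", "lee_dh_fp") +
      .racenum(f, c(mexican = 0.98, hispanic = 0.23, afro_descendant = -1.77, other = 0.08),
               "lee_dh_fp")),
  giro = function(d, o) {
    s4 <- .sk(d, "tr", "giro") + .sk(d, "si", "giro") + .sk(d, "ab", "giro") +
      .sk(d, "th", "giro")
    -0.620 + 0.159 * s4 + 0.120 * .need(d, "circ_waist", "giro")
  },
  cavedon1 = function(d, o)
    0.241 * .sk(d, "th", "cavedon1") + 0.418 * .sk(d, "ab", "cavedon1") +
      0.329 * .sk(d, "ss", "cavedon1") + 0.259 * .sk(d, "ax", "cavedon1") - 1.689,
  cavedon2 = function(d, o)
    0.162 * sum_skinfolds(d, c("bi", "tr", "ss", "ax", "ch", "si", "ab", "th", "c"),
                          "cavedon2") - 0.311
)

# Fat mass -------------------------------------------------------------------

.fm_fns <- list(
  al_guindan = function(d, o) .sex_split(
    d,
    function(m) 0.198 * .need(m, "body_weight_kg", "al_guindan") +
      0.478 * .need(m, "circ_waist", "al_guindan") -
      0.147 * .need(m, "height_cm", "al_guindan") - 12.8,
    function(f) 0.789 * .need(f, "body_weight_kg", "al_guindan") +
      0.0786 * .need(f, "age", "al_guindan") -
      0.342 * .need(f, "height_cm", "al_guindan") + 24.5),
  de_rose_fm = function(d, o) {
    s4 <- sum_skinfolds(d, c("ss", "tr", "ssp", "ab"), "de_rose_fm")
    0.01 * .need(d, "body_weight_kg", "de_rose_fm") * (s4 * 0.153 + 5.783)
  },
  isak5_fm = function(d, o) {
    h <- .need(d, "height_cm", "isak5_fm")
    s6 <- sum_skinfolds(d, c("tr", "ss", "si", "ab", "th", "c"), "isak5_fm")
    if (isTRUE(o$as_printed)) {
      (s6 * 5.85 + 25.6) / .kerr_scale(h)
    } else {
      z <- (s6 * (170.18 / h) - o$kerr_adipose_c1) / o$kerr_adipose_c2
      (z * 5.85 + 25.6) / .kerr_scale(h)
    }
  },
  heitmann = function(d, o) {
    bmi <- .cohort_bmi(d)
    bw <- .need(d, "body_weight_kg", "heitmann")
    age <- .need(d, "age", "heitmann")
    0.988 * bmi + .sexnum(d, 0.242, 0.344, "heitmann") * bw + 0.094 * age - 30.180
  },
  lee_dh_fm = function(d, o) .sex_split(
    d,
    function(m) -0.009 + 0.004 * .need(m, "age", "lee_dh_fm") -
      0.108 * .need(m, "height_cm", "lee_dh_fm") + 0.334 * .need(m, "body_weight_kg", "lee_dh_fm") +
      0.247 * .need(m, "circ_waist", "lee_dh_fm") - 0.306 * .need(m, "circ_arm", "lee_dh_fm") -
      0.075 * .need(m, "circ_calf", "lee_dh_fm") - 0.028 * .need(m, "circ_thigh", "lee_dh_fm") +
      0.307 * .sk(m, "tr", "lee_dh_fm") + 0.030 * .sk(m, "ss", "lee_dh_fm") +
      .racenum(m, c(mexican = 0.154, hispanic = -0.050, afro_descendant = -0.529, other = 0.687),
               "lee_dh_fm"),
    function(f) 8.633 + 0.048 * .need(f, "age", "lee_dh_fm") -
      0.166 * .need(f, "height_cm", "lee_dh_fm") + 0.569 * .need(f, "body_weight_kg", "lee_dh_fm") +
      0.044 * .need(f, "circ_waist", "lee_dh_fm") - 0.082 * .need(f, "circ_arm", "lee_dh_fm") -
      0.183 * .need(f, "circ_calf", "lee_dh_fm") + 0.115 * .need(f, "circ_thigh", "lee_dh_fm") +
      0.150 * .sk(f, "tr", "lee_dh_fm") + 0.008 * .sk(f, "ss", "lee_dh_fm") +
      .racenum(f, c(mexican = 0.357, hispanic = -0.071, afro_descendant = -1.345, other = 0.177),
               "lee_dh_fm")),
  salamat_fm = function(d, o)
    -11.938 + 1.606 * .cohort_bmi(d) - 8.511 * .sexnum(d, 1, 0, "salamat_fm")
)

# Lean mass ------------------------------------------------------------------

# Lee RC limb model shared by the LM and LP entries. Height in metres.
.lee_rc_limb <- function(d, o, id) {
  hm <- .need(d, "height_cm", id) / 100
  cac <- .cg(d, "circ_arm", "tr", o, id)
  cthc <- .cg(d, "circ_thigh", "th", o, id)
  ccc <- .cg(d, "circ_calf", "c", o, id)
  hm * (0.00744 * cac^2 + 0.00088 * cthc^2 + 0.00441 * ccc^2) +
    2.4 * .sexnum(d, 1, 0, id) - 0.048 * .need(d, "age", id) +
    .racenum(d, c(asian = -2, afro_descendant = 1.1, white = 0, hispanic = 0,
                  mexican = 0), id, fallback = 0) + 7.8
}

.isak5_lm <- function(d, o) {
  h <- .need(d, "height_cm", "isak5_lm")
  s5 <- .cg(d, "circ_arm", "tr", o, "isak5_lm") +
    .need(d, "circ_forearm", "isak5_lm") +
    .cg(d, "circ_thigh", "th", o, "isak5_lm") +
    .cg(d, "circ_calf", "c", o, "isak5_lm") +
    .cg(d, "circ_chest", "ss", o, "isak5_lm")
  zmus <- (s5 * (170.18 / h) - 207.21) / 13.74
  (zmus * 5.4 + 24.5) / .kerr_scale(h)
}

.lm_fns <- list(
  de_rose_lm = function(d, o) {
    bw <- .need(d, "body_weight_kg", "de_rose_lm")
    fm <- .fm_fns$de_rose_fm(d, o)
    hm <- .need(d, "height_cm", "de_rose_lm") / 100
    wd <- .need(d, "diam_wrist", "de_rose_lm") / 100
    fd <- .need(d, "diam_femur", "de_rose_lm") / 100
    bm <- 3.02 * (hm^2 * wd * fd * 400)^0.712
    rm <- 0.241 * bw
    bw - (fm + bm + rm)
  },
  heymsfield = function(d, o) {
    h <- .need(d, "height_cm", "heymsfield")
    ac <- .need(d, "circ_arm", "heymsfield")
    tr_cm <- .sk(d, "tr", "heymsfield") / 10
    area <- (ac - pi * tr_cm)^2 / (4 * pi) - .sexnum(d, 10, 6.5, "heymsfield")
    h * (o$heymsfield_coefficient + 0.0029 * area)
  },
  lee_rc_1 = function(d, o) .lee_rc_limb(d, o, "lee_rc_1"),
  lee_rc_2 = function(d, o) {
    0.244 * .need(d, "body_weight_kg", "lee_rc_2") +
      7.8 * .need(d, "height_cm", "lee_rc_2") / 100 +
      6.6 * .sexnum(d, 1, 0, "lee_rc_2") - 0.098 * .need(d, "age", "lee_rc_2") +
      .racenum(d, c(asian = -1.2, afro_descendant = 1.4, white = 0, hispanic = 0,
                    mexican = 0), "lee_rc_2", fallback = 0) - 3.3
  },
  doupe = function(d, o) {
    hm <- .need(d, "height_cm", "doupe") / 100
    cthc <- .cg(d, "circ_thigh", "th", o, "doupe")
    ccc <- .cg(d, "circ_calf", "c", o, "doupe")
    cac <- .cg(d, "circ_arm", "tr", o, "doupe")
    k <- if (isTRUE(o$as_printed)) 1 else 0.1
    hm * k * (0.031 * cthc^2 + 0.064 * ccc^2 + 0.089 * cac^2) - 3.006
  },
  isak5_lm = function(d, o) .isak5_lm(d, o),
  janmahasatian = function(d, o) {
    bw <- .need(d, "body_weight_kg", "janmahasatian")
    bmi <- .cohort_bmi(d)
    .sexnum(d, 1, 0, "janmahasatian") * (9270 * bw / (8780 + 244 * bmi)) +
      .sexnum(d, 0, 1, "janmahasatian") * (9270 * bw / (6680 + 216 * bmi))
  },
  olshvang = function(d, o) .sex_split(
    d,
    function(m) 19.363 + 0.001 * .need(m, "age", "olshvang") +
      0.064 * .need(m, "height_cm", "olshvang") + 0.756 * .need(m, "body_weight_kg", "olshvang") -
      0.366 * .need(m, "circ_waist", "olshvang") +
      .racenum(m, c(hispanic = 0.231, mexican = 0.231, afro_descendant = 0.432,
                    other = -1.007), "olshvang"),
    function(f) -10.683 - 0.039 * .need(f, "age", "olshvang") +
      0.186 * .need(f, "height_cm", "olshvang") + 0.383 * .need(f, "body_weight_kg", "olshvang") -
      0.043 * .need(f, "circ_waist", "olshvang") +
      .racenum(f, c(hispanic = -0.059, mexican = -0.059, afro_descendant = 1.085,
                    other = -0.34), "olshvang")),
  chien = function(d, o)
    27.479 + 0.726 * .need(d, "body_weight_kg", "chien") -
      3.383 * .sexnum(d, 1, 0, "chien") - 0.672 * .cohort_bmi(d) +
      0.514 * .need(d, "circ_forearm", "chien") - 0.245 * .need(d, "circ_hip", "chien"),
  lee_dh_lm = function(d, o) .sex_split(
    d,
    function(m) -1.401 - 0.010 * .need(m, "age", "lee_dh_lm") +
      0.100 * .need(m, "height_cm", "lee_dh_lm") + 0.632 * .need(m, "body_weight_kg", "lee_dh_lm") -
      0.225 * .need(m, "circ_waist", "lee_dh_lm") + 0.315 * .need(m, "circ_arm", "lee_dh_lm") +
      0.091 * .need(m, "circ_calf", "lee_dh_lm") + 0.040 * .need(m, "circ_thigh", "lee_dh_lm") -
      0.304 * .sk(m, "tr", "lee_dh_lm") - 0.021 * .sk(m, "ss", "lee_dh_lm") +
      .racenum(m, c(mexican = 0.120, hispanic = 0.097, afro_descendant = 0.463,
                    other = -0.661), "lee_dh_lm"),
    function(f) -9.193 - 0.045 * .need(f, "age", "lee_dh_lm") +
      0.158 * .need(f, "height_cm", "lee_dh_lm") + 0.410 * .need(f, "body_weight_kg", "lee_dh_lm") -
      0.040 * .need(f, "circ_waist", "lee_dh_lm") + 0.095 * .need(f, "circ_arm", "lee_dh_lm") +
      0.193 * .need(f, "circ_calf", "lee_dh_lm") - 0.105 * .need(f, "circ_thigh", "lee_dh_lm") -
      0.152 * .sk(f, "tr", "lee_dh_lm") - 0.004 * .sk(f, "ss", "lee_dh_lm") +
      .racenum(f, c(mexican = -0.306, hispanic = 0.082, afro_descendant = 1.235,
                    other = -0.196), "lee_dh_lm")),
  kulkarni3 = function(d, o) {
    s4 <- sum_skinfolds(d, c("bi", "tr", "ss", "si"), "kulkarni3")
    if (any(s4 <= 0)) stop("skinfold sum must be > 0 (log10 undefined)")
    .sex_split(
      d,
      function(m) 13.78 - 0.018 * m$age + 0.064 * m$height_cm + 0.697 * m$body_weight_kg -
        5.842 * log10(sum_skinfolds(m, c("bi", "tr", "ss", "si"), "kulkarni3")),
      function(f) 1.689 - 0.014 * f$age + 0.120 * f$height_cm + 0.499 * f$body_weight_kg -
        3.315 * log10(sum_skinfolds(f, c("bi", "tr", "ss", "si"), "kulkarni3")))
  },
  kulkarni4 = function(d, o) .sex_split(
    d,
    function(m) 10.385 - 0.005 * .need(m, "age", "kulkarni4") +
      0.103 * .need(m, "height_cm", "kulkarni4") + 0.680 * .need(m, "body_weight_kg", "kulkarni4") +
      0.288 * .need(m, "circ_arm", "kulkarni4") + 0.130 * .need(m, "circ_calf", "kulkarni4") -
      0.183 * .need(m, "circ_hip", "kulkarni4") -
      5.278 * log10(sum_skinfolds(m, c("bi", "tr", "ss", "si"), "kulkarni4")),
    function(f) 10.632 - 0.009 * .need(f, "age", "kulkarni4") +
      0.102 * .need(f, "height_cm", "kulkarni4") + 0.592 * .need(f, "body_weight_kg", "kulkarni4") +
      0.055 * .need(f, "circ_arm", "kulkarni4") + 0.043 * .need(f, "circ_calf", "kulkarni4") -
      0.158 * .need(f, "circ_hip", "kulkarni4") -
      3.174 * log10(sum_skinfolds(f, c("bi", "tr", "ss", "si"), "kulkarni4"))),
  salamat_lm = function(d, o)
    14.966 + 0.588 * .cohort_bmi(d) + 18.694 * .sexnum(d, 1, 0, "salamat_lm") +
      0.137 * .need(d, "circ_waist", "salamat_lm") - 0.138 * .need(d, "age", "salamat_lm")
)

# Lean percentage ------------------------------------------------------------

.lp_fns <- list(
  lee_rc_lp = function(d, o) {
    bw <- .need(d, "body_weight_kg", "lee_rc_lp")
    if (any(bw <= 0)) stop("body weight must be positive")
    .lee_rc_limb(d, o, "lee_rc_lp") / bw * 100
  },
  poortmans = function(d, o) {
    bw <- .need(d, "body_weight_kg", "poortmans")
    if (any(bw <= 0)) stop("body weight must be positive")
    if (isTRUE(o$as_printed)) {
      hm <- .need(d, "height_cm", "poortmans") / 100
      hm * (0.0264 * .need(d, "circ_arm", "poortmans")^2) +
        0.0032 * .need(d, "circ_thigh", "poortmans")^2 +
        0.0015 * .need(d, "circ_calf", "poortmans")^2 +
        2.56 * .sexnum(d, 1, 0, "poortmans") + 0.136 * .need(d, "age", "poortmans")
    } else {
      hm <- .need(d, "height_cm", "poortmans") / 100
      mm <- hm * (0.0064 * .cg(d, "circ_arm", "tr", o, "poortmans")^2 +
                    0.0032 * .cg(d, "circ_thigh", "th", o, "poortmans")^2 +
                    0.0015 * .cg(d, "circ_calf", "c", o, "poortmans")^2) +
        2.56 * .sexnum(d, 1, 0, "poortmans") + 0.136 * .need(d, "age", "poortmans")
      mm / bw * 100
    }
  },
  isak5_lp = function(d, o) {
    bw <- .need(d, "body_weight_kg", "isak5_lp")
    if (any(bw <= 0)) stop("body weight must be positive")
    .isak5_lm(d, o) / bw * 100
  }
)

# Family wrappers ------------------------------------------------------------

#' Estimate fat percentage, fat mass, lean percentage or lean mass
#'
#' `estimate_fp()` accepts either a direct fat-percentage equation id or a
#' composite `"<bd_equation>+<converter>"` (e.g. `"durnin_womersley+siri"`).
#' The other wrappers dispatch within their own family. All equations return
#' values in the output variable's conventional unit: percent on the 0-100
#' scale for FP/LP, kilograms for FM/LM.
#'
#' @param equation_id registry id; see [list_equations()].
#' @param cohort cohort data.frame.
#' @param opts an [anthro_options()] list.
#' @return Numeric vector, one estimate per subject.
#' @export
#' @examples
#' d <- data.frame(subject_id = "a", sex = "male", age = 30,
#'                 body_weight_kg = 70, height_cm = 170,
#'                 sk_tr = 11.8, sk_si = 23.07)
#' estimate_fp("hastuti", d)
estimate_fp <- function(equation_id, cohort, opts = anthro_options()) {
  if (grepl("+", equation_id, fixed = TRUE)) {
    parts <- strsplit(equation_id, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(.bd_fns) ||
        !parts[2] %in% c("siri", "brozek"))
      stop("unknown composite equation id: ", equation_id)
    return(as.numeric(bd_to_fp(parts[2], estimate_bd(parts[1], cohort, opts))))
  }
  fn <- .fp_fns[[match.arg(equation_id, names(.fp_fns))]]
  as.numeric(fn(cohort, opts))
}

#' @rdname estimate_fp
#' @export
estimate_fm <- function(equation_id, cohort, opts = anthro_options()) {
  fn <- .fm_fns[[match.arg(equation_id, names(.fm_fns))]]
  as.numeric(fn(cohort, opts))
}

#' @rdname estimate_fp
#' @export
estimate_lp <- function(equation_id, cohort, opts = anthro_options()) {
  fn <- .lp_fns[[match.arg(equation_id, names(.lp_fns))]]
  as.numeric(fn(cohort, opts))
}

#' @rdname estimate_fp
#' @export
estimate_lm <- function(equation_id, cohort, opts = anthro_options()) {
  fn <- .lm_fns[[match.arg(equation_id, names(.lm_fns))]]
  as.numeric(fn(cohort, opts))
}

#' Evaluate any registered equation by id
#'
#' @inheritParams estimate_fp
#' @return Numeric vector of estimates.
#' @export
estimate_composition <- function(equation_id, cohort, opts = anthro_options()) {
  reg <- equation_registry()
  row <- reg[reg$equation_id == equation_id, ]
  if (nrow(row) != 1) stop("unknown equation id: ", equation_id)
  switch(row$output,
         BD = estimate_bd(equation_id, cohort, opts),
         FP = estimate_fp(equation_id, cohort, opts),
         FM = estimate_fm(equation_id, cohort, opts),
         LP = estimate_lp(equation_id, cohort, opts),
         LM = estimate_lm(equation_id, cohort, opts))
}
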