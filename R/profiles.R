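# Cohort schema -------------------------------------------------------------
#
# A cohort is a plain data.frame, one row per subject. Units are canonical:
# skinfolds in mm, circumferences/diameters/height in cm, masses in kg.
# Missing optional measurements are NA, never zero.

#' Skinfold, circumference and diameter site codes
#'
#' Site abbreviations follow kinanthropometric convention: BI bicipital,
#' TR tricipital, SS subscapular, SI suprailiac, SSP supraspinal,
#' AB abdominal, TH front thigh, C medial calf, AX axillary, CH chest.
#'
#' @format Character vectors of site codes.
#' @name anthro_sites
#' @export
skinfold_sites <- c("bi", "tr", "ss", "si", "ssp", "ab", "th", "c", "ax", "ch")

#' @rdname anthro_sites
#' @export
circumference_sites <- c("arm", "forearm", "thigh", "calf", "chest", "waist", "hip")

#' @rdname anthro_sites
#' @export
diameter_sites <- c("wrist", "femur")

.sex_levels <- c("male", "female")
.race_levels <- c("white", "hispanic", "mexican", "afro_descendant", "asian", "other")
.amputation_levels <- c("transtibial", "transfemoral", "hip_disarticulation", "none")

.sk_cols <- paste0("sk_", skinfold_sites)
.circ_cols <- paste0("circ_", circumference_sites)
.diam_cols <- paste0("diam_", diameter_sites)
.ref_cols <- c("dexa_fp", "dexa_fm", "dexa_lp", "dexa_lm", "dexa_bmc")

#' Column names of the cohort table
#'
#' @param references logical; include the reference (DXA-style) columns.
#' @return Character vector of canonical column names.
#' @export
cohort_columns <- function(references = TRUE) {
  cols <- c("subject_id", "sex", "age", "race",
            "body_weight_kg", "height_cm", "bmi",
            .sk_cols, .circ_cols, .diam_cols,
            "amputation_level", "measured_side")
  if (references) cols <- c(cols, .ref_cols)
  cols
}

#' Validate a cohort table
#'
#' Checks the structural invariants of the subject table: canonical units
#' and column names, strictly positive lengths and skinfolds where present,
#' adult ages, plausible heights, reference fat/lean percentages inside
#' (0, 100) and reference masses below body weight.
#'
#' @param cohort data.frame with one row per subject (see [cohort_columns()]).
#' @param require_references logical; insist on complete DXA-style columns.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, require_references = FALSE) {
  stopifnot(is.data.frame(cohort))
  needed <- c("subject_id", "sex", "age", "body_weight_kg", "height_cm")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(cohort$sex) || !all(cohort$sex %in% .sex_levels))
    stop("sex must be one of: ", paste(.sex_levels, collapse = ", "))
  if ("race" %in% names(cohort) &&
      !all(is.na(cohort$race) | cohort$race %in% .race_levels))
    stop("race must be one of: ", paste(.race_levels, collapse = ", "))
  if ("amputation_level" %in% names(cohort) &&
      !all(is.na(cohort$amputation_level) |
             cohort$amputation_level %in% .amputation_levels))
    stop("amputation_level must be one of: ",
         paste(.amputation_levels, collapse = ", "))
  if (any(cohort$age < 18)) stop("all subjects must be adults (age >= 18)")
  if (any(cohort$height_cm < 100 | cohort$height_cm > 230))
    stop("height_cm must lie in [100, 230]")
  if (any(cohort$body_weight_kg <= 0)) stop("body_weight_kg must be positive")
  for (col in intersect(c(.sk_cols, .circ_cols, .diam_cols), names(cohort))) {
    v <- cohort[[col]]
    if (any(!is.na(v) & v <= 0))
      stop("column '", col, "' must be strictly positive where present")
  }
  if (require_references) {
    miss <- setdiff(.ref_cols, names(cohort))
    if (length(miss))
      stop("cohort is missing reference columns: ", paste(miss, collapse = ", "))
    if (any(cohort$dexa_fp <= 0 | cohort$dexa_fp >= 100))
      stop("dexa_fp must lie in (0, 100)")
    if (any(cohort$dexa_lp <= 0 | cohort$dexa_lp >= 100))
      stop("dexa_lp must lie in (0, 100)")
    if (any(cohort$dexa_fm >= cohort$body_weight_kg))
      stop("dexa_fm must be below body weight")
    if (any(cohort$dexa_lm >= cohort$body_weight_kg))
      stop("dexa_lm must be below body weight")
  }
  invisible(cohort)
}

# Derived quantities ---------------------------------------------------------

#' Body mass index
#'
#' `BMI = weight / (height/100)^2`, in kg/m^2.
#'
#' @param body_weight_kg body weight in kg.
#' @param height_cm standing height in cm.
#' @return Numeric vector of BMI values.
#' @export
#' @examples
#' compute_bmi(69.52, 167.63)
compute_bmi <- function(body_weight_kg, height_cm) {
  if (any(!is.finite(body_weight_kg)) || any(!is.finite(height_cm)) ||
      any(body_weight_kg <= 0) || any(height_cm <= 0))
    stop("body weight and height must be positive and finite")
  body_weight_kg / (height_cm / 100)^2
}

# BMI used by the equations: an explicit `bmi` column takes precedence over
# the value recomputed from weight and height (descriptive tables sometimes
# carry a BMI that is not exactly BW/H^2). Provenance is attached.
.cohort_bmi <- function(cohort) {
  if ("bmi" %in% names(cohort) && !anyNA(cohort$bmi)) {
    structure(cohort$bmi, provenance = "given")
  } else {
    structure(compute_bmi(cohort$body_weight_kg, cohort$height_cm),
              provenance = "computed")
  }
}

#' Sum of skinfolds over a named site list
#'
#' @param cohort cohort data.frame.
#' @param sites character vector of site codes (see [skinfold_sites]).
#' @param equation_id optional id used in error messages when a site needed
#'   by a particular equation is missing.
#' @return Numeric vector of per-subject sums in mm, with the site list used
#'   attached as attribute `"sites"`.
#' @export
#' @examples
#' d <- data.frame(sk_tr = 11.8, sk_ss = 18.3)
#' sum_skinfolds(d, c("tr", "ss"))
sum_skinfolds <- function(cohort, sites, equation_id = NULL) {
  sites <- match.arg(sites, skinfold_sites, several.ok = TRUE)
  cols <- paste0("sk_", sites)
  who <- if (is.null(equation_id)) "" else paste0(" (required by equation '", equation_id, "')")
  for (i in seq_along(cols)) {
    if (!cols[i] %in% names(cohort) || anyNA(cohort[[cols[i]]]))
      stop("skinfold site '", sites[i], "' is missing", who)
  }
  out <- Reduce(`+`, lapply(cols, function(cl) cohort[[cl]]))
  attr(out, "sites") <- sites
  out
}

#' Skinfold-corrected girth
#'
#' Subtracts the fold contribution from a limb circumference,
#' `c = girth - skinfold * 3.141 / 10` (skinfold in mm, girth in cm; the
#' division by 10 converts mm to cm). The 3.141 approximation of pi is used
#' by default to reproduce the printed arithmetic of the source compendium;
#' set `full_pi = TRUE` in [anthro_options()] for machine precision.
#'
#' @param circumference_cm raw girth in cm.
#' @param skinfold_mm skinfold at the correcting site in mm (zero allowed).
#' @param opts an [anthro_options()] list.
#' @return Corrected girth in cm.
#' @export
#' @examples
#' corrected_girth(32.05, 11.8)
corrected_girth <- function(circumference_cm, skinfold_mm, opts = anthro_options()) {
  if (any(!is.finite(circumference_cm)) || any(!is.finite(skinfold_mm)))
    stop("girth and skinfold must be present and finite")
  if (any(circumference_cm <= 0) || any(skinfold_mm < 0))
    stop("girth must be positive and skinfold non-negative")
  out <- circumference_cm - skinfold_mm * .pi_factor(opts) / 10
  if (any(out <= 0))
    stop("corrected girth <= 0: physically impossible girth/skinfold pair")
  out
}

# Corrected-girth shorthand used throughout the lean-mass equations:
# cAC (arm/triceps), cTHC (thigh/front-thigh), cCC (calf/medial-calf),
# cCHC (chest/subscapular).
.cg <- function(cohort, girth_col, sk_site, opts, equation_id) {
  sk <- .need(cohort, paste0("sk_", sk_site), equation_id)
  g <- .need(cohort, girth_col, equation_id)
  corrected_girth(g, sk, opts)
}

#' Derived measures for a cohort
#'
#' Convenience table of BMI, the common skinfold sums and the four corrected
#' girths, computed from the canonical columns.
#'
#' @param cohort cohort data.frame.
#' @param opts an [anthro_options()] list.
#' @return data.frame with one row per subject.
#' @export
derived_measures <- function(cohort, opts = anthro_options()) {
  bmi <- .cohort_bmi(cohort)
  out <- data.frame(subject_id = cohort$subject_id,
                    bmi_kg_m2 = as.numeric(bmi))
  attr(out$bmi_kg_m2, "provenance") <- attr(bmi, "provenance")
  sums <- list(sum4sk_dw = c("bi", "tr", "ss", "si"),
               sum6sk_kerr = c("tr", "ss", "si", "ab", "th", "c"))
  for (nm in names(sums)) {
    ok <- all(paste0("sk_", sums[[nm]]) %in% names(cohort)) &&
      !anyNA(cohort[paste0("sk_", sums[[nm]])])
    out[[nm]] <- if (ok) as.numeric(sum_skinfolds(cohort, sums[[nm]])) else NA_real_
  }
  cg_map <- list(c_arm = c("circ_arm", "tr"), c_thigh = c("circ_thigh", "th"),
                 c_calf = c("circ_calf", "c"), c_chest = c("circ_chest", "ss"))
  for (nm in names(cg_map)) {
    gc <- cg_map[[nm]][1]; sk <- paste0("sk_", cg_map[[nm]][2])
    ok <- all(c(gc, sk) %in% names(cohort)) && !anyNA(cohort[c(gc, sk)])
    out[[nm]] <- if (ok) corrected_girth(cohort[[gc]], cohort[[sk]], opts) else NA_real_
  }
  out
}

# I/O ------------------------------------------------------------------------

#' Read or write a cohort CSV
#'
#' The on-disk schema matches [cohort_columns()]: one row per subject, empty
#' cells mark missing optional measurements. Numbers are written with 17
#' significant digits so that a write/read round trip reproduces every value
#' exactly.
#'
#' @param path file path.
#' @param cohort cohort data.frame.
#' @return `read_cohort()` returns a validated cohort data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  num <- setdiff(names(d), c("subject_id", "sex", "race",
                             "amputation_level", "measured_side"))
  for (col in num) d[[col]] <- as.numeric(d[[col]])
  d$subject_id <- as.character(d$subject_id)
  validate_cohort(d)
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  for (col in names(out)) {
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.17g", out[[col]]))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Shared column accessor with an informative error naming the requester.
.need <- function(cohort, col, equation_id = NULL) {
  who <- if (is.null(equation_id)) "" else paste0(" (required by equation '", equation_id, "')")
  if (!col %in% names(cohort) || anyNA(cohort[[col]]))
    stop("measurement '", col, "' is missing", who)
  cohort[[col]]
}
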