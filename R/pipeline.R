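# Validation pipeline --------------------------------------------------------

#' Configuration of a validation run
#'
#' @param families subset of `c("FP", "FM", "LP", "LM")` to analyse.
#' @param alpha family-wise significance level (default 0.05).
#' @param family_sizes named Bonferroni family sizes. Defaults to the
#'   registry counts (FP 34, FM 6, LP 3, LM 13).
#' @param clinical_bias_limits named absolute-bias limits used by
#'   [recommend()]: percent-points for FP/LP, kg for FM/LM. A bias above
#'   1 percent-point in fat-percentage estimation is generally too large
#'   for practical use, hence the FP default.
#' @param strict logical; error (rather than skip) when an equation's
#'   inputs are unavailable.
#' @param opts an [anthro_options()] list.
#' @param seed optional integer recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(families = c("FP", "FM", "LP", "LM"),
                       alpha = 0.05,
                       family_sizes = NULL,
                       clinical_bias_limits = c(FP = 1.0, FM = 1.0,
                                                LP = 1.0, LM = 1.5),
                       strict = FALSE,
                       opts = anthro_options(),
                       seed = NULL) {
  families <- match.arg(families, c("FP", "FM", "LP", "LM"), several.ok = TRUE)
  if (!length(families)) stop("families must be non-empty")
  stopifnot(alpha > 0, alpha < 1, all(clinical_bias_limits > 0))
  if (is.null(family_sizes)) {
    reg <- list_equations()
    family_sizes <- vapply(c(FP = "FP", FM = "FM", LP = "LP", LM = "LM"),
                           function(f) sum(reg$output == f), numeric(1))
  }
  structure(list(families = families, alpha = alpha,
                 family_sizes = family_sizes,
                 clinical_bias_limits = clinical_bias_limits,
                 strict = strict, opts = opts, seed = seed),
            class = "run_config")
}

.ref_col_of <- c(FP = "dexa_fp", FM = "dexa_fm", LP = "dexa_lp", LM = "dexa_lm")

#' Run the full agreement battery on a cohort
#'
#' For every requested family, evaluates each registered equation on the
#' cohort, pairs the estimates with the reference column and computes the
#' complete agreement report row. Equations whose inputs are unavailable
#' are skipped with a logged reason (or raise an error under
#' `strict = TRUE`).
#'
#' @param cohort cohort data.frame including reference columns.
#' @param config a [run_config()].
#' @return List of class `validation_run` with elements `reports` (named
#'   list of per-family report data.frames), `summary` (per-equation mean
#'   and SD alongside the reference), `skipped` (data.frame of skipped
#'   equations and reasons), `config` and `n_subjects`.
#' @export
run_validation <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  validate_cohort(cohort, require_references = TRUE)
  reports <- list()
  summaries <- list()
  skipped <- data.frame(family = character(), equation_id = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (fam in config$families) {
    fam_eqs <- list_equations(fam)
    refv <- cohort[[.ref_col_of[[fam]]]]
    rows <- list()
    summaries[[fam]] <- data.frame(
      family = fam, equation_id = "reference",
      label = paste("Reference (DXA)", fam),
      mean = mean(refv), sd = sd(refv), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fam_eqs))) {
      id <- fam_eqs$equation_id[i]
      est <- tryCatch(estimate_composition(id, cohort, config$opts),
                      error = function(e) e)
      if (inherits(est, "error")) {
        if (config$strict) stop("equation '", id, "' failed: ",
                                conditionMessage(est))
        skipped <- rbind(skipped, data.frame(
          family = fam, equation_id = id,
          reason = conditionMessage(est), stringsAsFactors = FALSE))
        next
      }
      ps <- paired_sample(est, refv, family = fam, equation_id = id)
      row <- agreement_report(ps, m = config$family_sizes[[fam]],
                              alpha = config$alpha)
      row$label <- fam_eqs$label[i]
      rows[[id]] <- row
      summaries[[fam]] <- rbind(summaries[[fam]], data.frame(
        family = fam, equation_id = id, label = fam_eqs$label[i],
        mean = mean(est), sd = sd(est), stringsAsFactors = FALSE))
    }
    if (!length(rows))
      stop("family ", fam, ": every equation was skipped")
    reports[[fam]] <- do.call(rbind, rows)
    rownames(reports[[fam]]) <- NULL
  }
  structure(list(reports = reports,
                 summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 skipped = skipped, config = config,
                 n_subjects = nrow(cohort)),
            class = "validation_run")
}

#' Recommendation label for one report row
#'
#' Codifies the recommendation logic as an explicit rule cascade (the
#' narrative criteria of validation studies mix these thresholds
#' informally):
#'
#' * `recommended` — not significant after Bonferroni, absolute bias within
#'   the family's clinical limit, and almost-perfect absolute-agreement ICC;
#' * `acceptable_with_caution` — absolute-agreement ICC at least
#'   substantial and absolute bias within twice the clinical limit;
#' * `not_recommended` — otherwise.
#'
#' @param report_row one row of a family report from [run_validation()].
#' @param config a [run_config()] (supplies the clinical bias limits).
#' @return List with `label` and `reasons` (the rules that fired).
#' @export
recommend <- function(report_row, config = run_config()) {
  fam <- report_row$family
  limit <- config$clinical_bias_limits[[fam]]
  bands <- c("poor", "slight", "fair", "moderate", "substantial", "almost perfect")
  rank <- match(report_row$icc_abs_band, bands)
  reasons <- character()
  ok_sig <- !report_row$significant_after_bonferroni
  ok_bias <- abs(report_row$mean_diff) <= limit
  ok_icc <- rank == length(bands)
  reasons <- c(reasons,
               sprintf("bias %.2f vs clinical limit %.2f: %s",
                       report_row$mean_diff, limit,
                       if (ok_bias) "within" else "exceeded"),
               sprintf("Bonferroni-corrected difference: %s",
                       if (ok_sig) "not significant" else "significant"),
               sprintf("absolute-agreement ICC %.2f (%s)",
                       report_row$icc_absolute, report_row$icc_abs_band))
  label <- if (ok_sig && ok_bias && ok_icc) {
    "recommended"
  } else if (rank >= match("substantial", bands) &&
               abs(report_row$mean_diff) <= 2 * limit) {
    "acceptable_with_caution"
  } else {
    "not_recommended"
  }
  list(label = label, reasons = reasons)
}

#' Attach recommendation labels to a validation run
#'
#' @param run a `validation_run` from [run_validation()].
#' @return The run with a `recommendation` column added to every report.
#' @export
recommend_all <- function(run) {
  stopifnot(inherits(run, "validation_run"))
  for (fam in names(run$reports)) {
    rep_ <- run$reports[[fam]]
    rep_$recommendation <- vapply(seq_len(nrow(rep_)), function(i)
      recommend(rep_[i, ], run$config)$label, character(1))
    run$reports[[fam]] <- rep_
  }
  run
}

#' Export validation outputs
#'
#' Writes, under `dir`: one report CSV and JSON per family, a Bland-Altman
#' pair CSV per equation (for plotting), a summary CSV, the equation
#' registry as JSON, a run manifest (package version, R version, seed,
#' config) and a plain-text log. File naming is deterministic so a re-run
#' with the same cohort and config reproduces identical outputs.
#'
#' @param run a `validation_run` from [run_validation()].
#' @param cohort the cohort the run was computed from (for the
#'   Bland-Altman pair export).
#' @param dir output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
export_outputs <- function(run, cohort, dir) {
  stopifnot(inherits(run, "validation_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  wpath <- function(...) file.path(dir, paste0(...))
  for (fam in names(run$reports)) {
    p1 <- wpath("report_", fam, ".csv")
    write.csv(run$reports[[fam]], p1, row.names = FALSE)
    p2 <- wpath("report_", fam, ".json")
    jsonlite::write_json(run$reports[[fam]], p2, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p1, p2)
    refv <- cohort[[.ref_col_of[[fam]]]]
    for (id in run$reports[[fam]]$equation_id) {
      est <- estimate_composition(id, cohort, run$config$opts)
      ba <- bland_altman(paired_sample(est, refv, family = fam, equation_id = id))
      p <- wpath("bland_altman_", fam, "_", gsub("[^a-z0-9_]", "_", id), ".csv")
      write.csv(cbind(subject_id = cohort$subject_id, ba$pairs), p,
                row.names = FALSE)
      written <- c(written, p)
    }
  }
  p <- wpath("summary.csv")
  write.csv(run$summary, p, row.names = FALSE)
  written <- c(written, p)
  p <- wpath("skipped.csv")
  write.csv(run$skipped, p, row.names = FALSE)
  written <- c(written, p)
  p <- wpath("registry.json")
  registry_to_json(p)
  written <- c(written, p)
  manifest <- list(
    package = "anthroagree",
    package_version = as.character(utils::packageVersion("anthroagree")),
    r_version = R.version.string,
    seed = run$config$seed,
    families = run$config$families,
    alpha = run$config$alpha,
    family_sizes = as.list(run$config$family_sizes),
    clinical_bias_limits = as.list(run$config$clinical_bias_limits),
    n_subjects = run$n_subjects,
    bias_convention = "diff = reference - estimate (positive = equation underestimates)")
  p <- wpath("manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, p)
  p <- wpath("run.log")
  writeLines(c(
    sprintf("anthroagree validation run, %d subjects", run$n_subjects),
    sprintf("families: %s", paste(run$config$families, collapse = ", ")),
    sprintf("rows reported: %s",
            paste(vapply(run$reports, nrow, numeric(1)), collapse = ", ")),
    sprintf("rows skipped: %d", nrow(run$skipped)),
    if (nrow(run$skipped))
      sprintf("  skipped %s (%s): %s", run$skipped$equation_id,
              run$skipped$family, run$skipped$reason) else character()),
    p)
  written <- c(written, p)
  invisible(written)
}
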