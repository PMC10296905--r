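#' Configuration for a full analysis run
#'
#' Bundles every setting of the end-to-end pipeline: the input (a cohort CSV
#' path or a [synthetic_config()] to generate one), the eligibility preset,
#' the Cox covariate list, the forest and bootstrap settings, smoothing
#' span, guideline cutoffs, and the master seed. Round-trips through JSON
#' via [jsonlite::write_json()].
#'
#' @param input a cohort CSV path, a cohort `data.frame`, or a
#'   [synthetic_config()].
#' @param preset eligibility preset, `"ln_neg"` or `"ln_pos"`.
#' @param covariates Cox covariates for the descriptive hazard-ratio table.
#' @param rsf an [rsf_config()].
#' @param n_iter,fraction,span,persistence threshold-estimation settings.
#' @param cutoffs guideline cutoffs for fold changes.
#' @param by_race attempt race-specific thresholds; skipped automatically
#'   (with a logged reason) when any analysed race subset is below
#'   `min_race_n`.
#' @param min_race_n minimum per-race subset size.
#' @param out_dir optional output directory for report files.
#' @param seed master seed, applied to the forest and bootstrap.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(input,
                            preset = c("ln_neg", "ln_pos"),
                            covariates = c("risk_group", "race", "grade",
                                           "stage", "age", "chemo"),
                            rsf = rsf_config(),
                            n_iter = 10, fraction = 0.70,
                            span = 0.75, persistence = 5,
                            cutoffs = c(25, 30),
                            by_race = TRUE, min_race_n = 500,
                            out_dir = NULL, seed = 1L) {
  preset <- match.arg(preset)
  rsf$seed <- as.integer(seed)
  structure(list(input = input, preset = preset, covariates = covariates,
                 rsf = rsf, n_iter = n_iter, fraction = fraction,
                 span = span, persistence = persistence, cutoffs = cutoffs,
                 by_race = by_race, min_race_n = min_race_n,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full threshold analysis
#'
#' Executes the pipeline end to end: load or generate the cohort, apply the
#' eligibility filter, summarise the cohort, fit the descriptive Cox models
#' (hazard-ratio table plus concordance with and without the
#' recurrence-score risk classification), compute risk-group-stratified
#' chemotherapy hazard ratios, fit the counterfactual survival forest with
#' subsample-bootstrap threshold estimation (per race where subset sizes
#' allow), and compute fold changes at the guideline cutoffs. Stage
#' boundaries and seeds are logged via `message()`. Identical
#' (config, seed) pairs give identical reports. A stage failure marks the
#' report partial, names the failed stage, and skips downstream stages.
#'
#' @param config an [analysis_config()].
#' @return An `analysis_report` with components `cohort_summary`, `cox`,
#'   `c_index` (with/without the risk classification), `stratified_hr`,
#'   `benefit` (the `chemo_benefit` fit), `fold_changes`, `truth` (when the
#'   input was synthetic), and `provenance` (seed, settings, failed stage if
#'   any).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(provenance = list(
    seed = config$seed, preset = config$preset,
    version = as.character(utils::packageVersion("chemothresh")),
    settings = list(n_iter = config$n_iter, fraction = config$fraction,
                    span = config$span, persistence = config$persistence,
                    n_trees = config$rsf$n_trees, cutoffs = config$cutoffs),
    failed_stage = NULL))
  stage <- function(name, expr) {
    if (!is.null(report$provenance$failed_stage)) return(NULL)
    message("[stage] ", name, " (seed ", config$seed, ")")
    tryCatch(expr, error = function(e) {
      report$provenance$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      message("[stage] ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
  }

  input <- stage("load", {
    if (inherits(config$input, "synthetic_config")) {
      gen <- generate_cohort(config$input)
      report$truth <- gen$truth
      gen
    } else if (is.character(config$input)) {
      list(cohort = read_cohort(config$input), truth = NULL)
    } else {
      list(cohort = validate_cohort(config$input), truth = NULL)
    }
  })
  report$truth <- input$truth

  cohort <- stage("eligibility", {
    out <- apply_eligibility(input$cohort, eligibility_preset(config$preset))
    if (nrow(out) == 0) stop("no rows pass the eligibility filter")
    out
  })

  report$cohort_summary <- stage("summarize", summarize_cohort(cohort))

  report$cox <- stage("cox", fit_cox(cohort, config$covariates))
  report$c_index <- stage("c_index", {
    without <- fit_cox(cohort, setdiff(config$covariates, "risk_group"))
    c(with_rs = if (!is.null(report$cox)) report$cox$concordance
        else NA_real_,
      without_rs = without$concordance)
  })
  report$stratified_hr <- stage("stratified_hr", chemo_hr_by_group(cohort))

  report$benefit <- stage("threshold", {
    race_n <- table(cohort$race[!is.na(cohort$rs)])
    by_race <- config$by_race
    if (by_race) {
      small <- race_n[race_n < config$min_race_n]
      if (length(small) || length(race_n) < 3) {
        message("[stage] threshold: race-specific analysis skipped ",
                "(subset below ", config$min_race_n, ": ",
                paste(names(small), collapse = ", "), ")")
        by_race <- FALSE
      }
    }
    chemo_benefit(cohort, rsf_config = config$rsf, n_iter = config$n_iter,
                  fraction = config$fraction, span = config$span,
                  persistence = config$persistence, cutoffs = config$cutoffs,
                  by_race = by_race, min_race_n = config$min_race_n)
  })
  report$fold_changes <- if (!is.null(report$benefit))
    report$benefit$fold_changes else NULL

  report$partial <- !is.null(report$provenance$failed_stage)
  report <- structure(report, class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", x$provenance$preset, " preset, seed ",
      x$provenance$seed, ")\n", sep = "")
  if (x$partial)
    cat("  PARTIAL - failed stage:", x$provenance$failed_stage, "\n")
  if (!is.null(x$c_index))
    cat(sprintf("  Cox concordance: %.3f with risk classification, %.3f without\n",
                x$c_index["with_rs"], x$c_index["without_rs"]))
  if (!is.null(x$benefit)) print(summary(x$benefit))
  invisible(x)
}

# Serialise the report as JSON + CSV tables under out_dir.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$cohort_summary))
    utils::write.csv(report$cohort_summary,
                     file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
  if (!is.null(report$cox))
    utils::write.csv(report$cox$hr_table, file.path(out_dir, "cox_hr.csv"),
                     row.names = FALSE)
  if (!is.null(report$stratified_hr))
    utils::write.csv(report$stratified_hr,
                     file.path(out_dir, "stratified_hr.csv"), row.names = FALSE)
  if (!is.null(report$benefit)) {
    cv <- report$benefit$curves$rel_risk
    utils::write.csv(data.frame(rs = cv$rs_grid, rel_risk = cv$value),
                     file.path(out_dir, "rel_risk_curve.csv"), row.names = FALSE)
    est <- report$benefit$threshold
    json <- list(
      threshold = list(median = est$median, iqr = est$iqr,
                       point_estimate = est$point_estimate,
                       bootstrap_values = est$bootstrap_values,
                       n_iter = est$n_iter, fraction = est$fraction),
      c_index = as.list(report$c_index),
      fold_changes = lapply(report$fold_changes, unclass),
      provenance = report$provenance
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(out_dir)
}

#' Write the small worked fixture datasets used in validation
#'
#' Emits, under `out_dir`: an 8-patient Cox worked example (`cox8.csv`:
#' times 1-8, all events, one binary covariate), the 3-patient Nelson-Aalen
#' worked example (`na3.csv`), a 7-row eligibility fixture in which rows 2-7
#' each violate exactly one criterion (`eligibility7.csv`), a 5-score
#' fold-change fixture (`fold5.csv`), and a medium synthetic cohort with its
#' ground-truth sidecar (`cohort_medium.csv`, `cohort_medium_truth.json`).
#'
#' @param out_dir writable directory (created if needed).
#' @param seed seed for the medium synthetic cohort.
#' @param n_medium size of the medium cohort.
#' @return Named character vector of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n_medium = 2000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_row <- function(id, ...) {
    row <- list(id = id, age = 60L, race = "white", stage = "I",
                grade = "moderate", er_status = "positive",
                pr_status = "positive", subtype = "luminalA",
                ln_status = "negative", rs = 20L, chemo = "no_unknown",
                time_months = 60, event = "censored")
    mods <- list(...)
    row[names(mods)] <- mods
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  paths <- c(cox8 = file.path(out_dir, "cox8.csv"),
             na3 = file.path(out_dir, "na3.csv"),
             eligibility7 = file.path(out_dir, "eligibility7.csv"),
             fold5 = file.path(out_dir, "fold5.csv"),
             medium = file.path(out_dir, "cohort_medium.csv"),
             truth = file.path(out_dir, "cohort_medium_truth.json"))

  cox8 <- do.call(rbind, lapply(1:8, function(i)
    base_row(sprintf("C%02d", i), time_months = i, event = "bcss_death",
             chemo = if (i %% 2 == 0) "yes" else "no_unknown")))
  write_cohort(cox8, paths["cox8"])

  na3 <- do.call(rbind, lapply(1:3, function(i)
    base_row(sprintf("N%02d", i), time_months = i, event = "bcss_death")))
  write_cohort(na3, paths["na3"])

  elig <- rbind(
    base_row("E01"),
    base_row("E02", stage = "III"),
    base_row("E03", er_status = "negative"),
    base_row("E04", subtype = "luminalB"),
    base_row("E05", age = 34L),
    base_row("E06", age = 81L),
    base_row("E07", rs = NA_integer_)
  )
  write_cohort(elig, paths["eligibility7"])

  fold5 <- do.call(rbind, lapply(seq_along(c(10L, 20L, 26L, 31L, 35L)),
    function(i) base_row(sprintf("F%02d", i),
                         rs = c(10L, 20L, 26L, 31L, 35L)[i])))
  write_cohort(fold5, paths["fold5"])

  gen <- generate_cohort(synthetic_config(n_patients = n_medium, seed = seed))
  write_cohort(gen$cohort, paths["medium"])
  write_ground_truth(gen$truth, paths["truth"])

  invisible(paths)
}
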