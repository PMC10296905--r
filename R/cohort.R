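# Standard cohort CSV schema, in column order. `time_months` is follow-up in
# months (> 0); `event` is "bcss_death" (breast-cancer-specific death) or
# "censored"; `rs` is the integer recurrence score 0-100, blank when the
# assay was not run.
cohort_columns <- c("id", "age", "race", "stage", "grade", "er_status",
                    "pr_status", "subtype", "ln_status", "rs", "chemo",
                    "time_months", "event")

cohort_levels <- list(
  race = c("white", "black", "asian", "other"),
  stage = c("I", "II", "III", "IV"),
  grade = c("well", "moderate", "poor", "undifferentiated"),
  er_status = c("positive", "negative"),
  pr_status = c("positive", "negative"),
  subtype = c("luminalA", "luminalB", "pre2010"),
  ln_status = c("negative", "positive"),
  chemo = c("no_unknown", "yes"),
  event = c("bcss_death", "censored")
)

validate_cohort <- function(x, where = "cohort") {
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols))
    stop("schema error in ", where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(x) == 0) stop("empty cohort: ", where, call. = FALSE)
  bad_rows <- character()
  for (col in names(cohort_levels)) {
    vals <- x[[col]]
    bad <- !is.na(vals) & !(vals %in% cohort_levels[[col]])
    if (any(bad))
      bad_rows <- c(bad_rows, paste0("column '", col, "', row(s) ",
                                     paste(which(bad), collapse = ",")))
  }
  if (length(bad_rows))
    stop("unparseable category values: ", paste(bad_rows, collapse = "; "),
         call. = FALSE)
  if (anyDuplicated(x$id))
    stop("duplicate patient ids in ", where, call. = FALSE)
  if (any(!is.na(x$rs) & (x$rs < 0 | x$rs > 100)))
    stop("rs out of [0, 100] in ", where, call. = FALSE)
  if (any(is.na(x$time_months) | x$time_months <= 0))
    stop("time_months must be > 0 in ", where, call. = FALSE)
  invisible(x)
}

#' Read and write cohorts in the standard CSV schema
#'
#' The schema has one row per patient with columns (in order): `id`, `age`,
#' `race`, `stage`, `grade`, `er_status`, `pr_status`, `subtype`,
#' `ln_status`, `rs`, `chemo`, `time_months`, `event`. Missing recurrence
#' scores are empty fields and are preserved as `NA`. Category columns are
#' validated against their enumerations; offending rows are reported by
#' column and row number.
#'
#' @param path file path of a comma-separated, UTF-8, headered CSV.
#' @return `read_cohort()` returns a validated `data.frame`;
#'   `write_cohort()` writes `cohort` to `path` and returns it invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  if (nrow(x) == 0) stop("empty cohort: ", path, call. = FALSE)
  validate_cohort(x, where = path)
  x$rs <- as.integer(x$rs)
  x$age <- as.integer(x$age)
  attr(x, "provenance") <- path
  x[, cohort_columns]
}

#' @rdname read_cohort
#' @param cohort a cohort `data.frame` in the standard schema.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Eligibility criteria for cohort selection
#'
#' Constructs the filter applied before analysis. The defaults (and the
#' `"ln_neg"` preset) select the primary study population: ER-positive,
#' stage I or II, luminal A (HR+/HER2-) patients aged 35-80 inclusive with
#' a recorded recurrence score and negative lymph nodes. The `"ln_pos"`
#' preset is identical but requires positive lymph nodes.
#'
#' @param stages_allowed character vector of allowed stages.
#' @param er_required require ER-positive disease.
#' @param subtypes_allowed allowed tumour subtypes.
#' @param age_min,age_max inclusive age bounds in years.
#' @param ln_status_required `"negative"`, `"positive"`, or `NA` for no
#'   restriction.
#' @param rs_required require a non-missing recurrence score.
#' @param races_allowed races retained for analysis (registry rows with
#'   other codes are kept by the reader but excluded here); `NULL` disables
#'   the restriction.
#' @return An `eligibility_criteria` object.
#' @export
eligibility_criteria <- function(stages_allowed = c("I", "II"),
                                 er_required = TRUE,
                                 subtypes_allowed = "luminalA",
                                 age_min = 35, age_max = 80,
                                 ln_status_required = "negative",
                                 rs_required = TRUE,
                                 races_allowed = c("white", "black", "asian")) {
  if (age_min >= age_max) stop("age_min must be < age_max", call. = FALSE)
  structure(list(stages_allowed = stages_allowed, er_required = er_required,
                 subtypes_allowed = subtypes_allowed,
                 age_min = age_min, age_max = age_max,
                 ln_status_required = ln_status_required,
                 rs_required = rs_required, races_allowed = races_allowed),
            class = "eligibility_criteria")
}

#' @rdname eligibility_criteria
#' @param preset `"ln_neg"` or `"ln_pos"`.
#' @export
eligibility_preset <- function(preset = c("ln_neg", "ln_pos")) {
  preset <- match.arg(preset)
  eligibility_criteria(ln_status_required =
                         if (preset == "ln_neg") "negative" else "positive")
}

#' Apply eligibility criteria to a cohort
#'
#' Keeps exactly the rows satisfying every criterion; order is preserved and
#' the operation is idempotent. May return an empty cohort.
#'
#' @param cohort a cohort `data.frame`.
#' @param criteria an [eligibility_criteria()] object.
#' @return The filtered cohort.
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_preset("ln_neg")) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  keep <- cohort$stage %in% criteria$stages_allowed &
    cohort$age >= criteria$age_min & cohort$age <= criteria$age_max &
    cohort$subtype %in% criteria$subtypes_allowed
  if (criteria$er_required) keep <- keep & cohort$er_status == "positive"
  if (!is.na(criteria$ln_status_required))
    keep <- keep & cohort$ln_status == criteria$ln_status_required
  if (criteria$rs_required) keep <- keep & !is.na(cohort$rs)
  if (!is.null(criteria$races_allowed))
    keep <- keep & cohort$race %in% criteria$races_allowed
  cohort[which(keep), , drop = FALSE]
}

#' Classify recurrence scores into registry risk categories
#'
#' Uses the registry convention: low risk below 18, intermediate risk for
#' scores 18-30 inclusive, high risk above 30 (the three clauses partition
#' 0-100 only under the inclusive-intermediate reading). Missing scores map
#' to `NA` and are excluded from classification summaries.
#'
#' @param rs integer recurrence score(s) in \[0, 100\] (NA allowed).
#' @return A factor with levels `low`, `intermediate`, `high`.
#' @export
classify_risk <- function(rs) {
  if (any(!is.na(rs) & (rs < 0 | rs > 100)))
    stop("rs must lie in [0, 100]", call. = FALSE)
  out <- ifelse(is.na(rs), NA_character_,
                ifelse(rs < 18, "low", ifelse(rs <= 30, "intermediate", "high")))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Per-race descriptive summary of a cohort
#'
#' Computes, per race and overall: patient count, percentage in each
#' recurrence-score risk category (among scored patients), percentage
#' PR-positive, percentage treated with chemotherapy (note that registry
#' chemotherapy coding collapses "no" and "unknown", so the untreated
#' percentage is an upper bound), and the mean and median recurrence score.
#'
#' @param cohort a cohort `data.frame`.
#' @return A `data.frame` with one row per race plus an `overall` row;
#'   percentage columns sum to 100 within each row's risk block.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  one <- function(x, label) {
    rc <- classify_risk(x$rs)
    n_rc <- sum(!is.na(rc))
    pct <- function(cat) if (n_rc) 100 * sum(rc == cat, na.rm = TRUE) / n_rc else NA_real_
    data.frame(
      group = label, n = nrow(x),
      pct_low = pct("low"), pct_intermediate = pct("intermediate"),
      pct_high = pct("high"),
      pct_pr_positive = 100 * mean(x$pr_status == "positive"),
      pct_chemo = 100 * mean(x$chemo == "yes"),
      rs_mean = mean(x$rs, na.rm = TRUE),
      rs_median = stats::median(x$rs, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  groups <- lapply(unique(cohort$race), function(r)
    one(cohort[cohort$race == r, , drop = FALSE], r))
  out <- do.call(rbind, c(groups, list(one(cohort, "overall"))))
  rownames(out) <- NULL
  out
}
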