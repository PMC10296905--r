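# Internal: cohort -> model frame for survival fitting. Factors carry the
# reference levels used in the hazard-ratio tables (low risk group, white
# race, well-differentiated grade, stage I, untreated); age stays numeric.
cox_model_frame <- function(cohort, covariates) {
  mf <- data.frame(
    time = cohort$time_months,
    status = as.integer(cohort$event == "bcss_death")
  )
  for (v in covariates) {
    mf[[v]] <- switch(v,
      age = cohort$age,
      rs = cohort$rs,
      risk_group = stats::relevel(classify_risk(cohort$rs), ref = "low"),
      race = factor(cohort$race, levels = c("white", "black", "asian", "other")),
      grade = factor(cohort$grade,
                     levels = c("well", "moderate", "poor", "undifferentiated")),
      stage = factor(cohort$stage, levels = c("I", "II", "III", "IV")),
      chemo = factor(cohort$chemo, levels = c("no_unknown", "yes")),
      subtype = factor(cohort$subtype,
                       levels = c("luminalA", "luminalB", "pre2010")),
      {
        if (!v %in% names(cohort))
          stop("covariate not in cohort: ", v, call. = FALSE)
        cohort[[v]]
      })
  }
  droplevels(mf)
}

#' Fit a Cox proportional-hazards model on a cohort
#'
#' Wraps [survival::coxph()] (Efron tie correction) over the standard cohort
#' schema, expanding categorical covariates against fixed reference levels:
#' low recurrence-score risk group, white race, well-differentiated grade,
#' stage I, and no/unknown chemotherapy. Age enters as a continuous per-year
#' covariate. Hazard ratios are `exp(coef)` with Wald 95% intervals
#' `exp(coef +- 1.96 se)`.
#'
#' @param cohort a cohort `data.frame` in the standard schema.
#' @param covariates character vector naming model terms; recognised names
#'   are `age`, `rs`, `risk_group` (the 18/30 classification of `rs`),
#'   `race`, `grade`, `stage`, `chemo`, `subtype`, plus any raw cohort
#'   column.
#' @return An object of class `cox_fit`: the underlying `coxph` fit, the
#'   hazard-ratio table (`term`, `level`, `coef`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p`), Harrell's concordance, `n` and `n_events`.
#' @export
fit_cox <- function(cohort, covariates = c("risk_group", "race", "grade",
                                           "stage", "age", "chemo")) {
  mf <- cox_model_frame(cohort, covariates)
  complete <- stats::complete.cases(mf)
  mf <- mf[complete, , drop = FALSE]
  if (sum(mf$status) < 2) stop("need >= 2 events to fit", call. = FALSE)
  constant <- vapply(covariates, function(v)
    length(unique(mf[[v]])) < 2, logical(1))
  if (all(constant)) stop("no non-constant covariates", call. = FALSE)
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = mf, ties = "efron", model = TRUE)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox fit did not converge", call. = FALSE)
  co <- summary(fit)$coefficients
  term_names <- rownames(co)
  # split "raceblack" into term/level for categorical covariates
  term <- level <- term_names
  for (v in covariates) {
    hit <- startsWith(term_names, v) & term_names != v
    term[hit] <- v
    level[hit] <- substring(term_names[hit], nchar(v) + 1L)
    level[term_names == v] <- ""
    term[term_names == v] <- v
  }
  hr_table <- data.frame(
    term = term, level = level,
    coef = co[, "coef"], se = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(fit = fit, hr_table = hr_table,
                 concordance = unname(summary(fit)$concordance["C"]),
                 covariates = covariates,
                 n = nrow(mf), n_events = sum(mf$status)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  cat("  n =", x$n, " events =", x$n_events,
      " concordance =", round(x$concordance, digits), "\n\n")
  tab <- x$hr_table
  tab$hr <- round(tab$hr, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "level", "hr", "ci_low", "ci_high", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Harrell's concordance index of a fitted Cox model on a cohort
#'
#' Among usable patient pairs (the member with the shorter observed time had
#' an event), returns the fraction in which the higher predicted risk failed
#' first, counting ties in predicted risk as 1/2. Computed via
#' [survival::concordance()] on the model's linear predictor, so it can be
#' evaluated on the training cohort or on new data.
#'
#' @param fit a `cox_fit`.
#' @param cohort cohort to evaluate on; defaults to the training data.
#' @return Concordance fraction in \[0, 1\].
#' @export
concordance_index <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(cohort)) {
    mf <- fit$fit$model
    lp <- fit$fit$linear.predictors
    time <- mf[[1]][, "time"]; status <- mf[[1]][, "status"]
  } else {
    mf <- cox_model_frame(cohort, fit$covariates)
    mf <- mf[stats::complete.cases(mf), , drop = FALSE]
    lp <- unname(stats::predict(fit$fit, newdata = mf, type = "lp"))
    time <- mf$time; status <- mf$status
  }
  cfit <- survival::concordance(survival::Surv(time, status) ~ lp,
                                reverse = TRUE)
  n_usable <- sum(cfit$count[c("concordant", "discordant", "tied.x")])
  if (n_usable == 0) stop("no usable pairs: concordance undefined", call. = FALSE)
  unname(cfit$concordance)
}

#' Chemotherapy hazard ratio stratified by risk group (and race)
#'
#' Fits one univariate chemotherapy Cox model per stratum of the
#' recurrence-score risk classification, optionally within a race subset,
#' mirroring the stratified forest-plot comparison of treated versus
#' untreated patients. Strata with fewer than two events in either
#' chemotherapy arm are marked not estimable rather than raising an error.
#'
#' @param cohort a cohort `data.frame`.
#' @param race_subset optional race to restrict to.
#' @return A `data.frame` (class `stratified_hr`) with columns `risk_group`,
#'   `n`, `n_events`, `hr`, `ci_low`, `ci_high`, `p`, `estimable`.
#' @export
chemo_hr_by_group <- function(cohort, race_subset = NULL) {
  if (!is.null(race_subset))
    cohort <- cohort[cohort$race %in% race_subset, , drop = FALSE]
  rc <- classify_risk(cohort$rs)
  out <- lapply(levels(rc), function(g) {
    sub <- cohort[which(rc == g), , drop = FALSE]
    row <- data.frame(risk_group = g, n = nrow(sub),
                      n_events = sum(sub$event == "bcss_death"),
                      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, estimable = FALSE,
                      stringsAsFactors = FALSE)
    ev_by_arm <- tapply(sub$event == "bcss_death", sub$chemo, sum)
    ok <- length(ev_by_arm) == 2 && !any(is.na(ev_by_arm)) && all(ev_by_arm >= 2)
    if (ok) {
      f <- tryCatch(fit_cox(sub, covariates = "chemo"), error = function(e) NULL)
      if (!is.null(f)) {
        row[c("hr", "ci_low", "ci_high", "p")] <-
          f$hr_table[1, c("hr", "ci_low", "ci_high", "p")]
        row$estimable <- TRUE
      }
    }
    row
  })
  structure(do.call(rbind, out), class = c("stratified_hr", "data.frame"))
}

#' Two-sample rank test
#'
#' Two-sided rank-based comparison of two samples. The default unpaired mode
#' is the Wilcoxon rank-sum (Mann-Whitney) test: the exact null distribution
#' is used when both samples have at most 12 observations and no ties, and
#' the normal approximation with tie correction otherwise. A paired
#' signed-rank mode is available for genuinely paired data. When every value
#' in both samples is identical the test is degenerate and p = 1 is returned
#' by convention.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @param paired use the signed-rank test on paired differences.
#' @return A list with `statistic` (U for unpaired, V for paired),
#'   `p_value`, and `method`.
#' @export
rank_test <- function(sample_a, sample_b, paired = FALSE) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  if (all(c(sample_a, sample_b) == c(sample_a, sample_b)[1]))
    return(list(statistic = NA_real_, p_value = 1,
                method = "degenerate (all values identical)"))
  exact <- length(sample_a) <= 12 && length(sample_b) <= 12 &&
    !any(duplicated(c(sample_a, sample_b)))
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            paired = paired, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}
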