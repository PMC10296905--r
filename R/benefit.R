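#' Fit the chemotherapy-benefit threshold model
#'
#' The package's central estimator. A random survival forest is fitted to
#' the cohort on (recurrence score, race, age, chemotherapy); per-patient
#' counterfactual mortality scores `risk_yes` / `risk_no` are obtained by
#' forcing the treatment variable to each arm; the relative-risk curve
#' `risk_yes - risk_no` is smoothed against the score and the benefit
#' threshold is located where the smoothed curve first crosses zero and
#' stays non-positive. Uncertainty comes from a subsample bootstrap
#' (default 10 x 70%), optionally repeated within each race, and the
#' clinical implication is summarised as fold changes versus guideline
#' cutoffs (RS > 25 and RS > 30).
#'
#' @param cohort a cohort `data.frame` in the standard schema (see
#'   [read_cohort()]); rows with missing recurrence score are dropped.
#' @param rsf_config an [rsf_config()]; its `seed` is the master seed for
#'   all randomness in the fit.
#' @param n_iter,fraction subsample-bootstrap settings.
#' @param span,persistence smoothing fraction and zero-crossing persistence
#'   rule.
#' @param cutoffs guideline cutoffs for fold changes.
#' @param by_race also estimate per-race thresholds (each race subset must
#'   have at least `min_race_n` patients; smaller subsets are marked not
#'   estimable).
#' @param min_race_n minimum race-subset size for race-specific estimation.
#' @return An object of class `chemo_benefit` with components `model` (the
#'   fitted `rsf_model`), `risks` (per-patient counterfactual risks),
#'   `curves` (smoothed rel/avg/yes/no risk curves), `threshold` (a
#'   `threshold_estimate`), `by_race` (a `race_thresholds` or `NULL`),
#'   `fold_changes`, and a call/config echo.
#' @seealso [bootstrap_thresholds()], [counterfactual_risks()],
#'   [run_full_analysis()]
#' @export
chemo_benefit <- function(cohort, rsf_config = chemothresh::rsf_config(),
                          n_iter = 10, fraction = 0.70,
                          span = 0.75, persistence = 5,
                          cutoffs = c(25, 30),
                          by_race = FALSE, min_race_n = 500) {
  cohort <- cohort[!is.na(cohort$rs), , drop = FALSE]
  est <- bootstrap_thresholds(cohort, rsf_config, n_iter = n_iter,
                              fraction = fraction, span = span,
                              persistence = persistence,
                              point_estimate = TRUE)
  full <- threshold_pass(cohort, rsf_config, span, persistence)
  risks <- full$risks
  grid <- full$curve$rs_grid
  curves <- list(
    rel_risk = full$curve,
    avg_risk = smooth_curve(risks$rs, risks$avg_risk, span, grid, "avg_risk"),
    risk_yes = smooth_curve(risks$rs, risks$risk_yes, span, grid, "risk_yes"),
    risk_no = smooth_curve(risks$rs, risks$risk_no, span, grid, "risk_no")
  )
  races <- if (by_race)
    race_specific_thresholds(cohort, rsf_config, n_iter = n_iter,
                             fraction = fraction, span = span,
                             persistence = persistence, min_n = min_race_n)
  else NULL
  folds <- if (!est$no_threshold)
    lapply(cutoffs, function(cc) fold_change(cohort, est$median, cc))
  else list()
  structure(list(model = full$model, risks = risks, curves = curves,
                 threshold = est, by_race = races, fold_changes = folds,
                 cutoffs = cutoffs, n = nrow(cohort),
                 rsf_config = rsf_config,
                 settings = list(n_iter = n_iter, fraction = fraction,
                                 span = span, persistence = persistence)),
            class = "chemo_benefit")
}

#' @export
print.chemo_benefit <- function(x, ...) {
  cat("Chemotherapy-benefit threshold model (counterfactual survival forest)\n")
  cat("  n =", x$n, "patients;", x$rsf_config$n_trees, "trees;",
      sprintf("%d x %.0f%% subsample bootstrap\n", x$settings$n_iter,
              100 * x$settings$fraction))
  print(x$threshold)
  invisible(x)
}

#' @export
summary.chemo_benefit <- function(object, ...) {
  structure(list(fit = object), class = "summary.chemo_benefit")
}

#' @export
print.summary.chemo_benefit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$by_race)) {
    cat("\nrace-specific thresholds:\n")
    print(f$by_race)
  }
  if (length(f$fold_changes)) {
    cat("\nfold changes versus guideline cutoffs:\n")
    for (fc in f$fold_changes) print(fc)
  }
  invisible(x)
}

#' @export
coef.chemo_benefit <- function(object, ...) {
  out <- c(threshold = object$threshold$median)
  if (!is.null(object$by_race)) {
    for (r in names(object$by_race$estimates)) {
      e <- object$by_race$estimates[[r]]
      out[paste0("threshold_", r)] <- if (is.null(e)) NA_real_ else e$median
    }
  }
  out
}

#' Counterfactual risk predictions for new patients
#'
#' @param object a fitted `chemo_benefit` model.
#' @param newdata cohort rows to score; defaults to the training cohort's
#'   stored per-patient risks.
#' @param ... unused.
#' @return A `counterfactual_risk` data frame (`id`, `rs`, `race`,
#'   `risk_yes`, `risk_no`, `avg_risk`, `rel_risk`).
#' @export
predict.chemo_benefit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$risks)
  counterfactual_risks(object$model, newdata)
}

#' Plot the smoothed counterfactual risk curves
#'
#' Left panel: smoothed `risk_yes` and `risk_no` (and their average) against
#' the recurrence score. Right panel: the smoothed relative-risk curve with
#' the zero line and the estimated benefit threshold.
#'
#' @param x a fitted `chemo_benefit` model.
#' @param which `"both"`, `"average"` or `"relative"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.chemo_benefit <- function(x, which = c("both", "average", "relative"),
                               ...) {
  which <- match.arg(which)
  cv <- x$curves
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "average")) {
    rng <- range(cv$risk_yes$value, cv$risk_no$value)
    graphics::plot(cv$risk_no$rs_grid, cv$risk_no$value, type = "l",
                   ylim = rng, xlab = "recurrence score",
                   ylab = "ensemble mortality", col = "steelblue", ...)
    graphics::lines(cv$risk_yes$rs_grid, cv$risk_yes$value, col = "firebrick")
    graphics::lines(cv$avg_risk$rs_grid, cv$avg_risk$value, col = "grey40",
                    lty = 2)
    graphics::legend("topleft", bty = "n", lty = c(1, 1, 2),
                     col = c("steelblue", "firebrick", "grey40"),
                     legend = c("risk.no", "risk.yes", "average"))
  }
  if (which %in% c("both", "relative")) {
    graphics::plot(cv$rel_risk$rs_grid, cv$rel_risk$value, type = "l",
                   xlab = "recurrence score",
                   ylab = "relative risk (risk.yes - risk.no)", ...)
    graphics::abline(h = 0, lty = 3)
    if (!x$threshold$no_threshold)
      graphics::abline(v = x$threshold$median, col = "firebrick", lty = 2)
  }
  invisible(x)
}
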