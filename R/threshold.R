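#' Local-regression smoothing of risk against recurrence score
#'
#' Locally weighted linear regression (tricube kernel, nearest-neighbour
#' bandwidth) evaluated on a fixed grid: at each grid point the bandwidth is
#' the distance to the `floor(span * n)`-th nearest observation and the
#' fitted value is the intercept of the weighted least-squares line. This is
#' the classic first-degree loess smoother, coded directly so evaluation on
#' an arbitrary grid is exact and deterministic.
#'
#' @param rs_values numeric predictor (recurrence scores).
#' @param y_values numeric response, same length (e.g. per-patient
#'   `rel_risk`).
#' @param span smoothing fraction in (0, 1].
#' @param grid evaluation grid; default a 0.1-step grid over the
#'   \[2.5th, 97.5th\] percentile range of `rs_values` (smoothers are
#'   unstable in sparse score tails).
#' @param kind label for the curve: `"rel_risk"`, `"avg_risk"`,
#'   `"risk_yes"` or `"risk_no"`.
#' @return A `smoothed_curve`: list with `rs_grid`, `value`, `span`, `kind`.
#' @export
smooth_curve <- function(rs_values, y_values, span = 0.75, grid = NULL,
                         kind = c("rel_risk", "avg_risk", "risk_yes", "risk_no")) {
  kind <- match.arg(kind)
  n <- length(rs_values)
  if (n < 10) stop("need >= 10 points to smooth", call. = FALSE)
  if (length(y_values) != n) stop("rs_values and y_values differ in length",
                                  call. = FALSE)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  if (is.null(grid)) grid <- default_rs_grid(rs_values)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  q <- floor(n * span)
  if (q < 3) stop("span window holds fewer than 3 points", call. = FALSE)

  value <- vapply(grid, function(x0) {
    d <- abs(rs_values - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) return(mean(y_values[d == 0]))
    w <- pmax(0, 1 - (d / h)^3)^3
    sw <- sum(w)
    xb <- sum(w * rs_values) / sw
    yb <- sum(w * y_values) / sw
    sxx <- sum(w * (rs_values - xb)^2)
    if (sxx <= .Machine$double.eps * sum(w * rs_values^2 + 1))
      return(yb)
    b1 <- sum(w * (rs_values - xb) * (y_values - yb)) / sxx
    yb + b1 * (x0 - xb)
  }, numeric(1))

  structure(list(rs_grid = grid, value = value, span = span, kind = kind),
            class = "smoothed_curve")
}

# 0.1-step grid over the central [2.5%, 97.5%] score range (quantile type 7).
default_rs_grid <- function(rs_values, quantiles = c(0.025, 0.975),
                            step = 0.1) {
  qs <- stats::quantile(rs_values, quantiles, names = FALSE, type = 7)
  lo <- ceiling(qs[1] / step) * step
  hi <- floor(qs[2] / step) * step
  seq(lo, hi, by = step)
}

#' Locate the benefit threshold as a persistent zero crossing
#'
#' Scans a smoothed relative-risk curve for the score at which predicted
#' harm turns into persistent predicted benefit: the crossing is the
#' smallest grid score `t` at which the curve becomes non-positive and then
#' stays non-positive for every higher grid score in the searched range,
#' with at least `persistence` grid points at or beyond `t` (so dips too
#' close to the upper edge are not declared thresholds). Requiring the
#' benefit to persist through the top of the range reflects the working
#' model - once chemotherapy benefits a patient at some score, it should
#' benefit every patient with a higher score - and rejects the transient
#' below-zero excursions that smoothed noise produces under a null
#' treatment effect (these can span many RS units, so no fixed short
#' persistence window rejects them). A residual null hazard remains when
#' treatment assignment is strongly confounded; see the package vignette. The
#' returned threshold is linearly interpolated between the bracketing grid
#' points for sub-grid precision; a curve that is non-positive over the
#' entire range yields the lower grid edge (benefit everywhere in range).
#' No qualifying crossing is a valid outcome and yields `NA`.
#'
#' @param curve a `smoothed_curve` of kind `rel_risk`.
#' @param persistence minimum number of grid points (at the default
#'   0.1-step grid, tenths of an RS unit) in the terminal non-positive run.
#' @return The threshold score, or `NA_real_` when the curve never crosses
#'   persistently.
#' @export
find_crossing <- function(curve, persistence = 5) {
  stopifnot(inherits(curve, "smoothed_curve"))
  if (curve$kind != "rel_risk")
    stop("find_crossing expects a rel_risk curve", call. = FALSE)
  g <- curve$rs_grid
  v <- curve$value
  m <- length(g)
  if (v[m] > 0) return(NA_real_)
  start <- m
  while (start > 1 && v[start - 1] <= 0) start <- start - 1
  if (m - start + 1 < persistence + 1) return(NA_real_)
  if (start == 1) return(g[1])
  y1 <- v[start - 1]; y2 <- v[start]
  g[start - 1] + (g[start] - g[start - 1]) * y1 / (y1 - y2)
}

# Deterministic per-iteration seed scheme: master seed plus a fixed prime
# stride, folded into the 32-bit range.
derive_seeds <- function(master_seed, n_iter, stream = 0L) {
  as.integer((as.numeric(master_seed) + 99991 * stream +
                7919 * seq_len(n_iter)) %% .Machine$integer.max)
}

# One full pass: fit forest, counterfactual risks, smooth, locate crossing.
threshold_pass <- function(cohort, config, span, persistence, grid = NULL) {
  model <- fit_rsf(cohort, config)
  risks <- counterfactual_risks(model, cohort)
  curve <- smooth_curve(risks$rs, risks$rel_risk, span = span, grid = grid,
                        kind = "rel_risk")
  list(threshold = find_crossing(curve, persistence = persistence),
       curve = curve, risks = risks, model = model)
}

#' Subsample-bootstrap estimate of the chemotherapy-benefit threshold
#'
#' Repeats the full estimation pass on random subsamples of the cohort: each
#' iteration draws `fraction` of the rows (without replacement by default),
#' fits the survival forest, computes counterfactual risks, smooths the
#' relative-risk curve against the recurrence score and locates the
#' persistent zero crossing. The threshold distribution over iterations is
#' summarised by its median and interquartile range (linear-interpolation
#' quantiles, R type 7). Iterations whose curve never crosses contribute
#' `NA` and are excluded from the summary. A full-data point estimate is
#' computed alongside.
#'
#' Every source of randomness is derived from `rsf_config$seed` (or the
#' explicit `seeds` vector) by a fixed counter scheme, so the estimate is
#' reproducible from (cohort, config, seeds) and invariant to iteration
#' order.
#'
#' @param cohort a cohort `data.frame` (standard schema, non-missing `rs`).
#' @param rsf_config an [rsf_config()]; its `seed` is the master seed.
#' @param n_iter bootstrap iterations (reference analysis: 10).
#' @param fraction subsample fraction (reference analysis: 0.70).
#' @param seeds optional explicit per-iteration seeds (length `n_iter`).
#' @param span,persistence smoothing fraction and crossing-persistence rule,
#'   passed to [smooth_curve()] and [find_crossing()].
#' @param replace subsample with replacement instead of without.
#' @param point_estimate also run the pass on the full cohort.
#' @return A `threshold_estimate`: `point_estimate`, `bootstrap_values`
#'   (`NA` allowed), `median`, `iqr` (lower, upper), `n_iter`, `fraction`,
#'   `seeds`, `no_threshold` flag, and the full-data `curve` when computed.
#' @export
bootstrap_thresholds <- function(cohort, rsf_config = chemothresh::rsf_config(),
                                 n_iter = 10, fraction = 0.70, seeds = NULL,
                                 span = 0.75, persistence = 5,
                                 replace = FALSE, point_estimate = TRUE) {
  stopifnot(inherits(rsf_config, "rsf_config"))
  cohort <- cohort[!is.na(cohort$rs), , drop = FALSE]
  n <- nrow(cohort)
  m <- floor(fraction * n)
  if (m < 50) stop("cohort too small for subsample bootstrap", call. = FALSE)
  if (is.null(seeds)) seeds <- derive_seeds(rsf_config$seed, n_iter)
  if (length(seeds) != n_iter) stop("need one seed per iteration", call. = FALSE)

  values <- vapply(seq_len(n_iter), function(it) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seeds[it])
    idx <- sample.int(n, m, replace = replace)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    cfg <- rsf_config
    cfg$seed <- seeds[it]
    threshold_pass(cohort[idx, , drop = FALSE], cfg, span, persistence)$threshold
  }, numeric(1))

  full <- if (point_estimate)
    threshold_pass(cohort, rsf_config, span, persistence) else NULL

  ok <- values[!is.na(values)]
  structure(list(
    point_estimate = if (point_estimate) full$threshold else NA_real_,
    bootstrap_values = values,
    median = if (length(ok)) stats::median(ok) else NA_real_,
    iqr = if (length(ok)) stats::quantile(ok, c(0.25, 0.75), names = FALSE,
                                          type = 7) else c(NA_real_, NA_real_),
    n_iter = n_iter, fraction = fraction, seeds = seeds,
    n_crossed = length(ok),
    no_threshold = length(ok) == 0,
    curve = if (point_estimate) full$curve else NULL
  ), class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, digits = 2, ...) {
  cat("Chemotherapy-benefit threshold (subsample bootstrap)\n")
  if (x$no_threshold) {
    cat("  no persistent zero crossing in any of", x$n_iter, "iterations\n")
  } else {
    cat(sprintf("  median RS %.2f (IQR %.2f-%.2f) over %d/%d crossing iterations\n",
                x$median, x$iqr[1], x$iqr[2], x$n_crossed, x$n_iter))
    if (!is.na(x$point_estimate))
      cat(sprintf("  full-data point estimate: RS %.2f\n", x$point_estimate))
  }
  cat(sprintf("  %d x %.0f%% subsamples, seeds from master scheme\n",
              x$n_iter, 100 * x$fraction))
  invisible(x)
}

#' Race-specific benefit thresholds with pairwise comparisons
#'
#' Runs [bootstrap_thresholds()] independently on each race subset (white,
#' black, asian) present in the cohort and compares the bootstrap threshold
#' distributions pairwise with [rank_test()]. Race subsets smaller than
#' `min_n` are marked not estimable rather than raising an error.
#'
#' @inheritParams bootstrap_thresholds
#' @param min_n minimum race-subset size for estimation.
#' @return A `race_thresholds` object: per-race `threshold_estimate`s (or
#'   `NULL` when not estimable) and a `data.frame` of pairwise rank-test
#'   p-values on the bootstrap values.
#' @export
race_specific_thresholds <- function(cohort, rsf_config = chemothresh::rsf_config(),
                                     n_iter = 10, fraction = 0.70,
                                     span = 0.75, persistence = 5,
                                     min_n = 500, point_estimate = FALSE) {
  races <- c("white", "black", "asian")
  ests <- stats::setNames(vector("list", length(races)), races)
  for (r in seq_along(races)) {
    sub <- cohort[cohort$race == races[r] & !is.na(cohort$rs), , drop = FALSE]
    if (nrow(sub) < min_n) next
    cfg <- rsf_config
    cfg$seed <- derive_seeds(rsf_config$seed, 1L, stream = r)
    ests[[races[r]]] <- bootstrap_thresholds(sub, cfg, n_iter = n_iter,
                                             fraction = fraction, span = span,
                                             persistence = persistence,
                                             point_estimate = point_estimate)
  }
  pairs <- utils::combn(races, 2, simplify = FALSE)
  cmp <- do.call(rbind, lapply(pairs, function(p) {
    a <- ests[[p[1]]]; b <- ests[[p[2]]]
    pv <- NA_real_
    if (!is.null(a) && !is.null(b) && !a$no_threshold && !b$no_threshold)
      pv <- rank_test(a$bootstrap_values[!is.na(a$bootstrap_values)],
                      b$bootstrap_values[!is.na(b$bootstrap_values)])$p_value
    data.frame(race_a = p[1], race_b = p[2], p_value = pv,
               stringsAsFactors = FALSE)
  }))
  structure(list(estimates = ests, comparisons = cmp),
            class = "race_thresholds")
}

#' @export
print.race_thresholds <- function(x, ...) {
  for (r in names(x$estimates)) {
    e <- x$estimates[[r]]
    if (is.null(e)) {
      cat(sprintf("  %-6s not estimable (subset below minimum size)\n", r))
    } else if (e$no_threshold) {
      cat(sprintf("  %-6s no persistent crossing\n", r))
    } else {
      cat(sprintf("  %-6s median RS %.2f (IQR %.2f-%.2f)\n", r, e$median,
                  e$iqr[1], e$iqr[2]))
    }
  }
  cat("pairwise rank tests on bootstrap thresholds:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Fold change in the population recommended for chemotherapy
#'
#' Compares the number of patients whose recurrence score exceeds an
#' estimated benefit threshold with the number above a guideline cutoff
#' (RS > 25 or RS > 30 by convention): `fold = count(RS > threshold) /
#' count(RS > cutoff)`. Fold > 1 means more patients would be recommended
#' chemotherapy under the estimated threshold than under the guideline;
#' fold < 1 means fewer.
#'
#' @param cohort a cohort `data.frame`.
#' @param threshold estimated benefit threshold (RS units).
#' @param guideline_cutoff guideline cutoff (RS units).
#' @return A `fold_change` list: `threshold`, `guideline_cutoff`,
#'   `n_above_threshold`, `n_above_cutoff`, `fold`.
#' @export
fold_change <- function(cohort, threshold, guideline_cutoff = 25) {
  rs <- cohort$rs[!is.na(cohort$rs)]
  n_cut <- sum(rs > guideline_cutoff)
  if (n_cut == 0)
    stop("undefined fold: no patients above the guideline cutoff", call. = FALSE)
  n_thr <- sum(rs > threshold)
  structure(list(threshold = threshold, guideline_cutoff = guideline_cutoff,
                 n_above_threshold = n_thr, n_above_cutoff = n_cut,
                 fold = n_thr / n_cut),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%.2f-fold %s patients above threshold RS %.2f than above cutoff RS %s (%d vs %d)\n",
              x$fold, if (x$fold < 1) "fewer" else "more", x$threshold,
              format(x$guideline_cutoff), x$n_above_threshold, x$n_above_cutoff))
  invisible(x)
}
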