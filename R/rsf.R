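#' Configuration for the random survival forest
#'
#' Parameters of the survival forest used for counterfactual risk
#' prediction. Trees are grown on independent resamples, splits maximise the
#' log-rank statistic among `mtry` randomly chosen candidate features, and
#' terminal nodes carry Nelson-Aalen cumulative-hazard estimates; the
#' ensemble prediction averages the per-tree cumulative hazards.
#'
#' @param n_trees number of trees (the reference analysis uses 1000; the
#'   scaled validation profile uses 200).
#' @param features model features; must include the treatment variable
#'   (`chemo`) for counterfactual use.
#' @param mtry candidate features per split; default `ceiling(sqrt(p))`.
#' @param min_node_size minimum terminal node size (samples).
#' @param sample_fraction fraction of rows resampled per tree.
#' @param replace resample with replacement (classic bootstrap, in-bag
#'   expectation 63.2%) or without.
#' @param risk_scale `"mortality"` (sum of the ensemble cumulative hazard
#'   over the training event-time grid, the survival-forest convention) or
#'   `"cif"` (cumulative incidence `1 - S(horizon)` at a fixed horizon).
#' @param horizon months; only used when `risk_scale = "cif"`.
#' @param seed integer seed; fixed seed gives a bit-identical refit.
#' @return An `rsf_config` object.
#' @export
rsf_config <- function(n_trees = 1000,
                       features = c("rs", "race", "age", "chemo"),
                       mtry = ceiling(sqrt(length(features))),
                       min_node_size = 15,
                       sample_fraction = 1,
                       replace = TRUE,
                       risk_scale = c("mortality", "cif"),
                       horizon = 120,
                       seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  risk_scale <- match.arg(risk_scale)
  structure(list(n_trees = as.integer(n_trees), features = features,
                 mtry = as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 sample_fraction = sample_fraction, replace = replace,
                 risk_scale = risk_scale, horizon = horizon,
                 seed = as.integer(seed)),
            class = "rsf_config")
}

# Internal: cohort -> feature frame with fixed factor codings. Race is an
# unordered categorical split by level partition; rs and age are ordered
# numeric.
rsf_feature_frame <- function(cohort, features) {
  missing_feat <- setdiff(features, c(names(cohort), "risk_group"))
  if (length(missing_feat))
    stop("schema error: feature(s) not in cohort: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  x <- data.frame(row.names = seq_len(nrow(cohort)))
  for (v in features) {
    x[[v]] <- switch(v,
      race = factor(cohort$race, levels = c("white", "black", "asian", "other")),
      chemo = factor(cohort$chemo, levels = c("no_unknown", "yes")),
      risk_group = classify_risk(cohort$rs),
      cohort[[v]])
  }
  droplevels(x, except = which(names(x) == "chemo"))
}

#' Fit a random survival forest on a cohort
#'
#' Backed by [ranger::ranger()] with log-rank splitting, Nelson-Aalen
#' terminal-node cumulative hazards, and full-level partition splits for
#' unordered categoricals, run single-threaded so a fixed seed reproduces
#' the forest bit-identically.
#'
#' @param cohort a cohort `data.frame` with at least one event.
#' @param config an [rsf_config()].
#' @return An `rsf_model`: the fitted ensemble, the training event-time
#'   grid, the feature schema and a config echo.
#' @export
fit_rsf <- function(cohort, config = rsf_config()) {
  stopifnot(inherits(config, "rsf_config"))
  status <- as.integer(cohort$event == "bcss_death")
  if (sum(status) < 1) stop("unfittable: cohort has no events", call. = FALSE)
  x <- rsf_feature_frame(cohort, config$features)
  d <- cbind(time = cohort$time_months, status = status, x)
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(config$features, collapse = " + ")))
  forest <- ranger::ranger(
    fml, data = d,
    num.trees = config$n_trees, mtry = min(config$mtry, length(config$features)),
    min.node.size = config$min_node_size,
    sample.fraction = config$sample_fraction, replace = config$replace,
    splitrule = "logrank",
    respect.unordered.factors = "partition",
    seed = config$seed, num.threads = 1, verbose = FALSE
  )
  structure(list(forest = forest,
                 event_time_grid = forest$unique.death.times,
                 features = config$features,
                 feature_levels = lapply(x, levels),
                 config = config),
            class = "rsf_model")
}

#' @export
print.rsf_model <- function(x, ...) {
  cat("Random survival forest:", x$config$n_trees, "trees on features",
      paste(x$features, collapse = ", "), "\n")
  cat("  event-time grid:", length(x$event_time_grid), "points; mtry =",
      x$config$mtry, "; min node size =", x$config$min_node_size, "\n")
  invisible(x)
}

#' Ensemble mortality scores for patients
#'
#' For each patient the ensemble cumulative hazard is the average of the
#' per-tree terminal-node Nelson-Aalen cumulative hazards; the mortality
#' score is its sum over the training event-time grid (or, under
#' `risk_scale = "cif"`, the cumulative incidence at the configured
#' horizon). Predictions are deterministic given (model, input).
#'
#' @param model an `rsf_model`.
#' @param cohort cohort rows to score (standard schema).
#' @return Numeric vector of non-negative risk scores.
#' @export
predict_mortality <- function(model, cohort) {
  stopifnot(inherits(model, "rsf_model"))
  x <- rsf_feature_frame(cohort, model$features)
  for (v in names(model$feature_levels)) {
    lv <- model$feature_levels[[v]]
    if (!is.null(lv)) {
      bad <- !is.na(x[[v]]) & !(as.character(x[[v]]) %in% lv)
      if (any(bad))
        stop("schema mismatch in feature '", v, "': unseen level(s) ",
             paste(unique(as.character(x[[v]])[bad]), collapse = ", "),
             call. = FALSE)
      x[[v]] <- factor(as.character(x[[v]]), levels = lv)
    }
  }
  pr <- stats::predict(model$forest, data = x, num.threads = 1)
  chf <- pr$chf
  if (is.null(dim(chf))) chf <- matrix(chf, nrow = nrow(x))
  if (model$config$risk_scale == "mortality") {
    rowSums(chf)
  } else {
    surv <- pr$survival
    if (is.null(dim(surv))) surv <- matrix(surv, nrow = nrow(x))
    idx <- findInterval(model$config$horizon, model$event_time_grid)
    if (idx == 0) rep(0, nrow(x)) else 1 - surv[, idx]
  }
}

#' Counterfactual chemotherapy risks from a fitted forest
#'
#' For each patient, `risk_yes` is the predicted mortality with the
#' chemotherapy variable forced to `"yes"` and `risk_no` with it forced to
#' `"no_unknown"`, all other fields untouched; `avg_risk = (risk_yes +
#' risk_no)/2` and `rel_risk = risk_yes - risk_no`. A patient's factual
#' prediction equals whichever counterfactual matches their observed
#' treatment. Positive `rel_risk` means chemotherapy is predicted harmful
#' for that patient, negative means beneficial.
#'
#' @param model an `rsf_model` fitted with the treatment variable among its
#'   features (checked unless `require_treatment = FALSE`, which exists so
#'   the no-op behaviour of a treatment-blind model can be demonstrated).
#' @param cohort cohort rows to score.
#' @param require_treatment error if `chemo` is not a model feature.
#' @return A `data.frame` (class `counterfactual_risk`) with columns `id`,
#'   `rs`, `race`, `risk_yes`, `risk_no`, `avg_risk`, `rel_risk`.
#' @export
counterfactual_risks <- function(model, cohort, require_treatment = TRUE) {
  stopifnot(inherits(model, "rsf_model"))
  if (require_treatment && !("chemo" %in% model$features))
    stop("model was fitted without the treatment variable 'chemo'; ",
         "counterfactual risks are undefined", call. = FALSE)
  yes <- cohort; yes$chemo <- "yes"
  no <- cohort; no$chemo <- "no_unknown"
  risk_yes <- predict_mortality(model, yes)
  risk_no <- predict_mortality(model, no)
  structure(data.frame(id = cohort$id, rs = cohort$rs, race = cohort$race,
                       risk_yes = risk_yes, risk_no = risk_no,
                       avg_risk = (risk_yes + risk_no) / 2,
                       rel_risk = risk_yes - risk_no,
                       stringsAsFactors = FALSE),
            class = c("counterfactual_risk", "data.frame"))
}

#' Save / load a fitted forest
#'
#' Persists the `rsf_model` (ensemble, event-time grid, feature schema and
#' config echo) to a single archive file; reloading reproduces predictions
#' bit-exactly.
#'
#' @param model an `rsf_model`.
#' @param path file path.
#' @return `save_rsf()` returns `path` invisibly; `load_rsf()` the model.
#' @export
save_rsf <- function(model, path) {
  stopifnot(inherits(model, "rsf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rsf
#' @export
load_rsf <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rsf_model"))
  model
}
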