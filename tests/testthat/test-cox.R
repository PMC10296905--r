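test_that("Cox fit recovers a known log-hazard ratio from two-arm data", {
  set.seed(101)
  cohort <- two_arm_cohort(400, beta = 0.7)
  fit <- fit_cox(cohort, covariates = "chemo")
  est <- fit$hr_table$coef[1]
  se <- fit$hr_table$se[1]
  expect_lt(abs(est - 0.7), 3 * se)
  # HR columns are exact transforms of coef and se
  expect_equal(fit$hr_table$hr, exp(fit$hr_table$coef))
  expect_equal(fit$hr_table$ci_low, exp(fit$hr_table$coef - 1.96 * fit$hr_table$se))
  expect_equal(fit$hr_table$ci_high, exp(fit$hr_table$coef + 1.96 * fit$hr_table$se))
})

test_that("permuted treatment labels are null at close to nominal level", {
  set.seed(202)
  cohort <- two_arm_cohort(400, beta = 0.7)
  hits <- 0L
  for (rep in 1:100) {
    perm <- cohort
    perm$chemo <- sample(perm$chemo)
    f <- fit_cox(perm, covariates = "chemo")
    if (abs(f$hr_table$coef[1]) > 2 * f$hr_table$se[1]) hits <- hits + 1L
  }
  expect_lte(hits, 10)  # 5% nominal plus binomial margin
})

test_that("8-patient fit matches a brute-force partial-likelihood grid", {
  cohort <- do.call(rbind, lapply(1:8, function(i)
    patient_row(sprintf("W%02d", i), time_months = i, event = "bcss_death",
                chemo = if (i %in% c(1, 3, 5, 8)) "yes" else "no_unknown")))
  fit <- fit_cox(cohort, covariates = "chemo")
  x <- as.integer(cohort$chemo == "yes")
  grid <- seq(-3, 3, by = 1e-4)
  nll <- vapply(grid, neg_log_partial_likelihood, numeric(1),
                time = cohort$time_months, status = rep(1L, 8), x = x)
  expect_lt(abs(fit$hr_table$coef[1] - grid[which.min(nll)]), 1e-3)
})

test_that("partial likelihood is maximised at the returned coefficients", {
  set.seed(303)
  for (rep in 1:5) {
    cohort <- two_arm_cohort(18, beta = runif(1, -1, 1))
    fit <- tryCatch(fit_cox(cohort, covariates = "chemo"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    b_hat <- fit$hr_table$coef[1]
    x <- as.integer(cohort$chemo == "yes")
    nll_hat <- neg_log_partial_likelihood(b_hat, cohort$time_months,
                                          rep(1L, nrow(cohort)), x)
    for (b in b_hat + seq(-0.5, 0.5, by = 0.1)) {
      expect_gte(neg_log_partial_likelihood(b, cohort$time_months,
                                            rep(1L, nrow(cohort)), x) + 1e-9,
                 nll_hat)
    }
  }
})

test_that("concordance equals brute-force pair enumeration", {
  set.seed(404)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    cohort <- two_arm_cohort(n, beta = 0.5, censor_rate = 0.02)
    fit <- fit_cox(cohort, covariates = "chemo")
    mf <- fit$fit$model
    cidx <- concordance_index(fit)
    bf <- brute_force_concordance(mf[[1]][, "time"], mf[[1]][, "status"],
                                  fit$fit$linear.predictors)
    expect_equal(cidx, bf, tolerance = 1e-12)
  }
})

test_that("concordance hits its analytic extremes", {
  # perfect reverse ranking of event times: concordance 1
  set.seed(505)
  n <- 30
  time <- sort(runif(n, 1, 100))
  cohort <- do.call(rbind, lapply(seq_len(n), function(i)
    patient_row(sprintf("P%02d", i), time_months = time[i],
                event = "bcss_death", rs = as.integer(100 - i))))
  fit <- suppressWarnings(fit_cox(cohort, covariates = "rs"))
  expect_equal(concordance_index(fit), 1)
  # risk constant in the evaluation cohort: all pairs tied, concordance 1/2
  flat <- cohort
  flat$rs <- 50L
  expect_equal(concordance_index(fit, flat), 0.5)
})

test_that("adding the risk classification does not hurt concordance", {
  g <- generate_cohort(synthetic_config(n_patients = 4000, seed = 81))$cohort
  with_rs <- suppressMessages(fit_cox(g, c("risk_group", "race", "age", "chemo")))
  without_rs <- suppressMessages(fit_cox(g, c("race", "age", "chemo")))
  expect_gte(with_rs$concordance, without_rs$concordance)
})

test_that("stratified chemotherapy HR reflects the benefit threshold", {
  g <- generate_cohort(synthetic_config(n_patients = 12000, theta = 25,
                                        benefit_slope = 0.02, seed = 91))$cohort
  tab <- chemo_hr_by_group(g)
  expect_identical(tab$risk_group, c("low", "intermediate", "high"))
  expect_true(all(tab$estimable))
  # below the threshold chemotherapy is harmful, above it beneficial
  expect_lt(tab$hr[tab$risk_group == "high"], tab$hr[tab$risk_group == "low"])
  # CI bounds bracket the point estimates
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
})

test_that("under a null treatment effect stratum CIs usually contain 1", {
  covered <- 0L
  total <- 0L
  for (rep in 1:20) {
    g <- generate_cohort(synthetic_config(n_patients = 2000, benefit_slope = 0,
                                          seed = 700 + rep))$cohort
    tab <- chemo_hr_by_group(g)
    est <- tab[tab$estimable, , drop = FALSE]
    covered <- covered + sum(est$ci_low <= 1 & est$ci_high >= 1)
    total <- total + nrow(est)
  }
  expect_gte(covered / total, 0.9)
})

test_that("strata without treated patients are marked not estimable", {
  g <- generate_cohort(synthetic_config(n_patients = 2000, seed = 92))$cohort
  g$chemo[classify_risk(g$rs) == "high"] <- "no_unknown"
  tab <- chemo_hr_by_group(g)
  expect_false(tab$estimable[tab$risk_group == "high"])
  expect_true(is.na(tab$hr[tab$risk_group == "high"]))
})

test_that("rank test gives exact small-sample p-values and is symmetric", {
  # fully separated samples: U = 0, exact two-sided p = 2 / choose(20, 10)
  rt <- rank_test(1:10, 11:20)
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 2 / choose(20, 10))
  # symmetry of the two-sided p under sample swap
  set.seed(606)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(rank_test(a, b)$p_value, rank_test(b, a)$p_value)
  # degenerate identical data
  expect_equal(rank_test(rep(1, 5), rep(1, 7))$p_value, 1)
  expect_equal(rank_test(c(3, 1, 2), c(3, 1, 2))$p_value, 1)
  expect_error(rank_test(numeric(0), 1:3), "non-empty")
})
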