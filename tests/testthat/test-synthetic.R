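test_that("invalid configurations are rejected naming the offending field", {
  expect_error(synthetic_config(race_mix = c(white = 0.5, black = 0.4, asian = 0.2)),
               "race_mix")
  expect_error(synthetic_config(lambda0 = 0), "lambda0")
  expect_error(synthetic_config(theta = c(white = 120, black = 25, asian = 25)),
               "theta")
  expect_error(synthetic_config(benefit_slope = -0.1), "benefit_slope")
  expect_error(synthetic_config(censor_time_max = -5), "censor_time_max")
})

test_that("generation is bit-identical for equal config and seed", {
  cfg <- synthetic_config(n_patients = 500, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(synthetic_config(n_patients = 500, seed = 12))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("null treatment effect leaves event times independent of arm", {
  cfg <- synthetic_config(n_patients = 5000, benefit_slope = 0,
                          propensity_a = -1, propensity_b = 0,
                          dropout_rate = 0, seed = 21)
  g <- generate_cohort(cfg)
  # chemo fraction approximately plogis(a)
  expect_lt(abs(mean(g$cohort$chemo == "yes") - plogis(-1)), 0.03)
  # event times exchangeable across arms among uncensored patients
  ev <- g$cohort[g$cohort$event == "bcss_death", ]
  p <- rank_test(ev$time_months[ev$chemo == "yes"],
                 ev$time_months[ev$chemo == "no_unknown"])$p_value
  expect_gt(p, 0.01)
})

test_that("empirical event fraction matches an independent Monte-Carlo oracle", {
  cfg <- synthetic_config(n_patients = 10000, lambda0 = 0.002, beta_rs = 0.03,
                          benefit_slope = 0.02, theta = 25,
                          censor_time_max = 120, seed = 31)
  g <- generate_cohort(cfg)
  emp <- mean(g$cohort$event == "bcss_death")

  # Oracle: 10^6 covariate draws, event probability under competing
  # exponential dropout and administrative censoring computed in closed form
  # per draw - a separate code path from the generator.
  set.seed(777)
  n_mc <- 1e6
  race <- sample(c("white", "black", "asian"), n_mc, TRUE,
                 prob = cfg$race_mix)
  rs <- round(qnorm(pnorm(0, cfg$rs_mean[race], cfg$rs_sd[race]) +
                      runif(n_mc) * (pnorm(100, cfg$rs_mean[race], cfg$rs_sd[race]) -
                                       pnorm(0, cfg$rs_mean[race], cfg$rs_sd[race])),
                    cfg$rs_mean[race], cfg$rs_sd[race]))
  age <- sample(35:80, n_mc, TRUE)
  chemo <- rbinom(n_mc, 1, plogis(cfg$propensity_a + cfg$propensity_b * rs))
  lam <- cfg$lambda0 * exp(cfg$beta_rs * rs + cfg$beta_age * (age - 60) / 10 +
                             chemo * (-cfg$benefit_slope * (rs - 25)))
  d <- cfg$dropout_rate
  p_event <- mean(lam / (lam + d) * (1 - exp(-(lam + d) * cfg$censor_time_max)))
  expect_lt(abs(emp - p_event), 0.03)
})

test_that("true relative risk has the threshold sign structure", {
  cfg <- synthetic_config(theta = c(white = 25, black = 37, asian = 18))
  # exactly zero at the race's own threshold, for several horizons
  for (h in c(12, 60, 120)) {
    expect_identical(true_relative_risk(cfg, 25, "white", horizon = h), 0)
    expect_identical(true_relative_risk(cfg, 37, "black", horizon = h), 0)
  }
  # sign equals sign(theta - rs) everywhere when the slope is positive
  rs <- 0:100
  for (race in c("white", "black", "asian")) {
    rr <- true_relative_risk(cfg, rs, race)
    expect_identical(sign(rr), sign(cfg$theta[[race]] - rs))
  }
  # no effect anywhere under a null slope
  null_cfg <- synthetic_config(benefit_slope = 0)
  expect_identical(true_relative_risk(null_cfg, rs, "white"), rep(0, 101))
})

test_that("true relative risk matches a quadrature oracle to 1e-10", {
  cfg <- synthetic_config(lambda0 = 0.002, beta_rs = 0.03, benefit_slope = 0.02,
                          theta = 25)
  rs <- 35; age <- 60; horizon <- 120
  # oracle: integrate each arm's event-time density numerically
  cum_inc <- function(lam) stats::integrate(function(t) lam * exp(-lam * t),
                                            0, horizon, rel.tol = 1e-13)$value
  eta0 <- cfg$beta_rs * rs
  gam <- -cfg$benefit_slope * (rs - 25)
  oracle <- cum_inc(cfg$lambda0 * exp(eta0 + gam)) - cum_inc(cfg$lambda0 * exp(eta0))
  expect_lt(abs(true_relative_risk(cfg, rs, "white", age, horizon) - oracle),
            1e-10)
})

test_that("Kaplan-Meier on a homogeneous no-censoring cohort matches the model", {
  # fix covariates: one race, point RS and age distributions
  cfg <- synthetic_config(n_patients = 20000,
                          race_mix = c(white = 1, black = 0, asian = 0),
                          rs_mean = c(white = 20, black = 20, asian = 20),
                          rs_sd = 1e-6, age_range = c(60L, 61L),
                          propensity_b = 0, propensity_a = -20,  # no chemo
                          dropout_rate = 0, censor_time_max = 240,
                          round_months = FALSE, seed = 41)
  g <- generate_cohort(cfg)
  expect_true(all(g$cohort$rs == 20))
  km <- survival::survfit(survival::Surv(time_months, event == "bcss_death") ~ 1,
                          data = g$cohort)
  # survival is a mixture over the two integer ages actually drawn
  lam <- function(a) cfg$lambda0 * exp(cfg$beta_rs * 20 + cfg$beta_age * (a - 60) / 10)
  w60 <- mean(g$cohort$age == 60)
  s_model <- sapply(km$time, function(t)
    w60 * exp(-lam(60) * t) + (1 - w60) * exp(-lam(61) * t))
  expect_lt(max(abs(km$surv - s_model)), 0.02)
})

test_that("chemotherapy uptake is non-decreasing in the propensity slope", {
  fracs <- sapply(c(0, 0.04, 0.08), function(b) {
    g <- generate_cohort(synthetic_config(n_patients = 10000, propensity_b = b,
                                          seed = 51))
    mean(g$cohort$chemo == "yes")
  })
  expect_true(all(diff(fracs) >= 0))
})

test_that("ground truth round-trips through its JSON sidecar", {
  cfg <- synthetic_config(n_patients = 100, theta = c(white = 20, black = 37,
                                                      asian = 18), seed = 61)
  g <- generate_cohort(cfg)
  path <- tempfile(fileext = ".json")
  write_ground_truth(g$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$theta, g$truth$theta)
  expect_equal(back$hazard_model_params, g$truth$hazard_model_params)
})
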