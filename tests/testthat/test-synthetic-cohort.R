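# Synthetic register cohort generator: calibration, invariants, ground truth.

test_that("covariate marginals match their configured targets", {
  cfg <- dgp_config()
  cov <- generate_covariates(cfg, 100000, seed = 5)
  # published full-population cells
  expect_lt(abs(mean(cov$female) - 0.49), 3 * sqrt(0.49 * 0.51 / 1e5))
  expect_lt(abs(mean(cov$homeowner) - 0.76), 3 * sqrt(0.76 * 0.24 / 1e5))
  expect_lt(abs(mean(cov$mother_working) - 0.71), 3 * sqrt(0.71 * 0.29 / 1e5))
  expect_lt(abs(mean(cov$single_parent) - 0.11), 3 * sqrt(0.11 * 0.89 / 1e5))
  expect_lt(abs(mean(cov$household_size) - 4.55), 0.02)
  expect_lt(abs(mean(cov$household_earnings) - 26300), 3 * 17400 / sqrt(1e5))
  expect_lt(abs(mean(cov$hospital_visits_4_6) - 0.51), 3 * sqrt(0.51 / 1e5))
  expect_lt(abs(mean(cov$birth_year) - 1985.5), 0.03)
  # composite SES index is standardized by construction
  expect_lt(abs(mean(cov$ses_index)), 0.02)
  expect_lt(abs(sd(cov$ses_index) - 1), 0.03)
  # all 38 modifiers present
  expect_true(all(modifier_names(cfg) %in% names(cov)))
  expect_length(modifier_names(cfg), 38)
})

test_that("zero SES loadings give independent covariates", {
  spec <- lapply(default_covariate_spec <- dgp_config()$covariate_spec,
                 function(s) { s$loading <- 0; s })
  cfg <- dgp_config(covariate_spec = spec)
  cov <- generate_covariates(cfg, 20000, seed = 6)
  pairs <- list(c("mother_edu", "homeowner"),
                c("household_earnings", "any_social_assistance"),
                c("father_working", "overcrowded"))
  for (p in pairs)
    expect_lt(abs(cor(cov[[p[1]]], cov[[p[2]]])), 0.03)
})

test_that("generation is deterministic in the seed", {
  cfg <- small_config()
  a <- simulate_cohort(cfg, seed = 3)
  b <- simulate_cohort(cfg, seed = 3)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 4)
  expect_false(identical(a$female, c2$female))
})

test_that("treatment assignment honors counts and tilts", {
  cfg <- small_config(n_treated = 500, n_control_pool = 9500)
  cov <- generate_covariates(cfg, 10000, seed = 7)

  # all-zero model: treated covariate means equal pool means within MC error
  cfg0 <- small_config(n_treated = 500, n_control_pool = 9500,
                       treatment_model = c(female = 0))
  t0 <- assign_treatment(cov, cfg0, seed = 8)
  expect_equal(sum(t0$treated), 500)
  se <- sqrt(0.49 * 0.51 / 500)
  expect_lt(abs(mean(t0$female[t0$treated == 1]) - mean(t0$female)), 3.5 * se)

  # positive hospital-visit coefficient raises the treated mean
  t1 <- assign_treatment(cov, cfg, seed = 8)
  expect_gt(mean(t1$hospital_visits_4_6[t1$treated == 1]),
            mean(t1$hospital_visits_4_6[t1$treated == 0]))

  # boundary: everyone treated
  cfg_all <- small_config(n_treated = 10000, n_control_pool = 0)
  t2 <- assign_treatment(cov, cfg_all, seed = 8)
  expect_equal(sum(t2$treated), 10000)

  # more treated than persons
  cfg_over <- small_config(n_treated = 10001, n_control_pool = 0)
  expect_error(assign_treatment(cov, cfg_over, seed = 8), "exceeds")
})

test_that("outcome invariants hold: survivorship, censoring, income coding", {
  cfg <- dgp_config(n_treated = 1000, n_control_pool = 30000)
  coh <- simulate_cohort(cfg, seed = 9)
  dead <- coh$died_by_30 == 1
  for (on in c("antidepressant_use", "no_partnership", "basic_education_only",
               "unemployment_months_annualized", "income_annual"))
    expect_true(all(is.na(coh[[on]][dead])), label = paste(on, "missing for deceased"))
  cens <- coh$birth_year %in% cfg$censor_cohorts
  expect_true(all(is.na(coh$antidepressant_use[cens])))
  expect_true(all(is.na(coh$income_annual[cens])))
  expect_true(any(!is.na(coh$no_partnership[cens & !dead])))
  u <- coh$unemployment_months_annualized
  expect_true(all(u[!is.na(u)] >= 0 & u[!is.na(u)] <= 12))
  inc <- coh$income_annual[!is.na(coh$income_annual)]
  expect_true(all(inc %% cfg$income_rounding == 0))
  expect_true(all(inc <= cfg$income_topcode))
})

test_that("null treatment effects produce equal group outcome means", {
  om <- dgp_config()$outcome_models
  for (on in names(om)) {
    om[[on]]$effect$base <- 0
    om[[on]]$effect$modifiers <- NULL
  }
  cfg <- dgp_config(n_treated = 4000, n_control_pool = 40000,
                    outcome_models = om)
  coh <- simulate_cohort(cfg, seed = 10)
  expect_equal(unique(true_cate(coh, cfg, "antidepressant_use")), 0)
  for (on in c("died_by_30", "no_partnership",
               "unemployment_months_annualized")) {
    y <- coh[[on]]
    t <- y[coh$treated == 1 & !is.na(y)]
    c0 <- y[coh$treated == 0 & !is.na(y)]
    z <- (mean(t) - mean(c0)) /
      sqrt(var(t) / length(t) + var(c0) / length(c0))
    expect_lt(abs(z), 4)
  }
})

test_that("the sex-modified antidepressant effect has the configured size", {
  cfg <- dgp_config(n_treated = 20000, n_control_pool = 60000)
  coh <- simulate_cohort(cfg, seed = 11)
  ok <- !is.na(coh$antidepressant_use)
  gap <- function(fem) {
    sel <- ok & coh$female == fem
    mean(coh$antidepressant_use[sel & coh$treated == 1]) -
      mean(coh$antidepressant_use[sel & coh$treated == 0])
  }
  delta <- cfg$outcome_models$antidepressant_use$effect$modifiers[["female"]]
  # additive probability-scale effects: the female-male gap difference is
  # delta_female exactly in expectation
  expect_lt(abs((gap(1) - gap(0)) - delta), 0.025)
})

test_that("true_cate matches a brute-force potential-outcome simulation", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 12)
  pars <- attr(coh, "outcome_params")
  set.seed(99)
  persons <- sample(nrow(coh), 20)
  reps <- 1e6

  # binary outcome with a modifier
  tau <- true_cate(coh, cfg, "antidepressant_use")
  p0 <- plogis(pars$antidepressant_use$intercept +
                 pars$antidepressant_use$ses_coef * coh$ses_index)
  for (i in persons[1:10]) {
    y1 <- rbinom(reps, 1, min(max(p0[i] + tau[i], 0), 1))
    y0 <- rbinom(reps, 1, p0[i])
    est <- mean(y1) - mean(y0)
    mc_se <- sqrt(2 * 0.25 / reps) + sqrt(var(y1) / reps + var(y0) / reps)
    expect_lt(abs(est - tau[i]), 3 * mc_se + 1e-6)
  }

  # zero-inflated unemployment: effect flows through the any-unemployment part
  up <- pars$unemployment_months_annualized
  tau_u <- true_cate(coh, cfg, "unemployment_months_annualized")
  expect_equal(unique(tau_u),
               cfg$outcome_models$unemployment_months_annualized$effect$base)
  pi0 <- plogis(up$intercept + up$ses_coef * coh$ses_index)
  for (i in persons[1:5]) {
    draw <- function(p) rbinom(reps, 1, min(max(p, 0), 1)) *
      12 * rbeta(reps, up$beta_a, up$beta_b)
    u1 <- draw(pi0[i] + up$dpi); u0 <- draw(pi0[i])
    est <- mean(u1) - mean(u0)
    mc_se <- sqrt(var(u1) / reps + var(u0) / reps)
    expect_lt(abs(est - tau_u[i]), 3 * mc_se)
  }

  # constant-effect model: tau is identically the base effect
  tau_inc <- true_cate(coh, cfg, "income_annual")
  expect_equal(unique(tau_inc), cfg$outcome_models$income_annual$effect$base)
  expect_error(true_cate(coh, cfg, "nonexistent"), "no configured model")
})

test_that("calibration_report has the documented shape and guards", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg, seed = 13)
  ex <- apply_exclusions(coh)
  m <- match_controls(ex$cohort, seed = 13)
  rep <- calibration_report(coh, m)
  expect_equal(nrow(rep), 6 + 11)
  expect_true(all(c("treated", "matched", "full") %in% names(rep)))
  expect_false(anyNA(rep$treated))
  coh0 <- coh[coh$treated == 0, ]
  expect_error(calibration_report(coh0), "no treated observations")
})

test_that("configs validate their inputs and round-trip through YAML", {
  expect_error(dgp_config(treatment_model = c(not_a_cov = 1)),
               "unknown covariate")
  expect_error(dgp_config(income_topcode = -1), "positive")
  expect_error(dgp_config(n_treated = 0), "at least 1")
  om <- default_outcome_models()
  om$no_partnership$effect$modifiers <- c(bogus = 0.1)
  expect_error(dgp_config(outcome_models = om), "unknown covariate")

  cfg <- small_config()
  path <- tempfile(fileext = ".yaml")
  write_dgp_config(cfg, path)
  cfg2 <- read_dgp_config(path)
  expect_equal(cfg2$ses_norm, cfg$ses_norm)
  expect_identical(simulate_cohort(cfg, seed = 2)$income_annual,
                   simulate_cohort(cfg2, seed = 2)$income_annual)
})

test_that("cohorts round-trip through CSV", {
  cfg <- small_config(n_treated = 30, n_control_pool = 400)
  coh <- simulate_cohort(cfg, seed = 14)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$income_annual, coh$income_annual)
  expect_equal(back$region, coh$region)
})
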