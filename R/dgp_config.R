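# Data-generating-process configuration for the synthetic register cohort.
#
# Covariates follow a single-latent-factor model: a standard-normal family
# socioeconomic factor Z drives all cross-covariate correlation through
# per-covariate loadings; marginals are calibrated exactly (intercepts solved
# by Gaussian quadrature, analytic where possible), so sample means match the
# configured targets up to Monte-Carlo error only.

cov_binary <- function(name, mean, loading = 0)
  list(name = name, type = "binary", mean = mean, loading = loading)
cov_normal <- function(name, mean, sd, loading = 0)
  list(name = name, type = "normal", mean = mean, sd = sd, loading = loading)
cov_lognormal <- function(name, mean, sdlog, loading = 0)
  list(name = name, type = "lognormal", mean = mean, sdlog = sdlog, loading = loading)
cov_poisson <- function(name, mean, loading = 0, shift = 0)
  list(name = name, type = "poisson", mean = mean, loading = loading, shift = shift)
cov_ordinal <- function(name, probs, loading = 0)
  list(name = name, type = "ordinal", probs = probs, loading = loading)
cov_logitnormal <- function(name, mean, spread, loading = 0)
  list(name = name, type = "logitnormal", mean = mean, spread = spread, loading = loading)
cov_uniform_int <- function(name, values)
  list(name = name, type = "uniform_int", values = values, loading = 0)

# quadrature grid over the standard normal latent
quad_grid <- function() {
  z <- seq(-8, 8, length.out = 2001)
  w <- stats::dnorm(z)
  list(z = z, w = w / sum(w))
}

solve_mean_intercept <- function(target, scale, grid) {
  # alpha such that E[plogis(alpha + scale * U)] = target, U ~ N(0,1)
  if (abs(scale) < 1e-12) return(stats::qlogis(target))
  f <- function(a) sum(grid$w * stats::plogis(a + scale * grid$z)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}

# conditional mean E[X | Z = z] and marginal moments per covariate type
cov_moments <- function(sp, grid) {
  lam <- sp$loading
  switch(sp$type,
    binary = {
      a <- solve_mean_intercept(sp$mean, lam, grid)
      g <- stats::plogis(a + lam * grid$z)
      m2 <- sum(grid$w * g)                       # == mean; Bernoulli: E[X^2|z]=g
      list(mean = sp$mean, sd = sqrt(sp$mean * (1 - sp$mean)),
           intercept = a, g = g)
    },
    normal = list(mean = sp$mean, sd = sp$sd, g = sp$mean + sp$sd * lam * grid$z),
    lognormal = {
      s <- sp$sdlog
      g <- sp$mean * exp(s * lam * grid$z - s^2 * lam^2 / 2)
      list(mean = sp$mean, sd = sp$mean * sqrt(exp(s^2) - 1), g = g)
    },
    poisson = {
      mu <- sp$mean - sp$shift
      if (mu <= 0) stop("poisson covariate mean must exceed shift")
      a <- log(mu) - lam^2 / 2
      g <- sp$shift + exp(a + lam * grid$z)
      v <- mu + mu^2 * (exp(lam^2) - 1)
      list(mean = sp$mean, sd = sqrt(v), intercept = a, g = g)
    },
    ordinal = {
      k <- seq_along(sp$probs)
      cuts <- stats::qnorm(cumsum(sp$probs))[-length(sp$probs)]
      resid <- sqrt(max(1 - lam^2, 1e-12))
      pk <- sapply(grid$z, function(z) {
        cd <- stats::pnorm((cuts - lam * z) / resid)
        diff(c(0, cd, 1))
      })
      g <- as.numeric(crossprod(pk, k))
      m <- sum(k * sp$probs)
      list(mean = m, sd = sqrt(sum(k^2 * sp$probs) - m^2), cuts = cuts, g = g)
    },
    logitnormal = {
      a <- solve_mean_intercept(sp$mean, sp$spread, grid)
      # conditional mean requires integrating the residual normal
      resid <- sqrt(max(1 - lam^2, 1e-12))
      sub <- quad_sub()
      g <- sapply(grid$z, function(z)
        sum(sub$w * stats::plogis(a + sp$spread * (lam * z + resid * sub$z))))
      m2 <- sum(grid$w * sapply(grid$z, function(z)
        sum(sub$w * stats::plogis(a + sp$spread * (lam * z + resid * sub$z))^2)))
      list(mean = sp$mean, sd = sqrt(max(m2 - sp$mean^2, 1e-12)),
           intercept = a, g = g)
    },
    uniform_int = {
      v <- sp$values
      list(mean = mean(v), sd = sqrt(mean(v^2) - mean(v)^2),
           g = rep(mean(v), length(grid$z)))
    },
    stop("unknown covariate type: ", sp$type))
}

quad_sub <- function() {
  z <- seq(-8, 8, length.out = 201)
  w <- stats::dnorm(z)
  list(z = z, w = w / sum(w))
}

default_covariate_spec <- function() {
  list(
    cov_binary("female", 0.49, 0),
    cov_binary("finnish_language", 0.94, 0.10),
    cov_poisson("hospital_visits_4_6", 0.51, 0),
    cov_normal("mother_age", 34.0, 5.2, 0.25),
    cov_ordinal("mother_edu", c(0.18, 0.32, 0.28, 0.14, 0.08), 0.65),
    cov_binary("mother_edu_health", 0.12, 0.15),
    cov_binary("mother_working", 0.71, 0.35),
    cov_poisson("mother_hospital_visits", 0.80, -0.15),
    cov_binary("mother_married", 0.78, 0.30),
    cov_normal("father_age", 36.5, 6.0, 0.25),
    cov_ordinal("father_edu", c(0.22, 0.34, 0.24, 0.12, 0.08), 0.65),
    cov_binary("father_edu_health", 0.03, 0.10),
    cov_binary("father_working", 0.84, 0.45),
    cov_poisson("father_hospital_visits", 0.50, -0.15),
    cov_binary("missing_parent", 0.05, -0.25),
    cov_binary("household_diabetes", 0.02, 0),
    cov_poisson("n_children", 2.66, 0, shift = 1),
    cov_binary("single_parent", 0.11, -0.40),
    cov_lognormal("household_assets", 21237, 1.10, 0.50),
    cov_lognormal("household_debts", 15000, 1.00, 0.10),
    cov_binary("any_social_assistance", 0.11, -0.70),
    cov_binary("any_home_care_allowance", 0.35, -0.10),
    cov_binary("any_unemployment_benefit", 0.25, -0.50),
    cov_lognormal("household_earnings", 26300, 0.60, 0.55),
    cov_binary("any_business_income", 0.15, 0.10),
    cov_binary("any_pension_income", 0.08, -0.20),
    cov_binary("any_sickness_allowance", 0.10, -0.15),
    cov_binary("any_parental_allowance", 0.30, 0.05),
    cov_binary("overcrowded", 0.15, -0.45),
    cov_binary("housing_flat", 0.35, -0.30),
    cov_binary("homeowner", 0.76, 0.55),
    cov_logitnormal("postcode_share_foreign", 0.02, 0.8, -0.10),
    cov_logitnormal("postcode_share_unemployed", 0.12, 0.5, -0.30),
    cov_logitnormal("postcode_share_low_edu", 0.45, 0.4, -0.35),
    cov_logitnormal("postcode_share_swedish", 0.05, 1.2, 0.05),
    cov_ordinal("remoteness", c(0.25, 0.15, 0.15, 0.12, 0.12, 0.11, 0.10), -0.10),
    cov_uniform_int("birth_year", 1981:1990)
  )
}

# household_size = n_children + 2 - single_parent is derived, completing the
# 38 modifiers together with the 37 drawn columns.
derived_covariates <- function() "household_size"

father_imputed_covariates <- function()
  c("father_age", "father_edu", "father_edu_health", "father_working",
    "father_hospital_visits")

# Coefficients are per standard deviation of the covariate. The female
# coefficient (-0.123 per SD ~ -0.25 per unit) reproduces the published
# treated-group share of women (~0.43 against 0.49 in the full population).
default_treatment_model <- function()
  c(female = -0.123, hospital_visits_4_6 = 0.20, household_diabetes = 0.50,
    n_children = 0.08)

default_outcome_models <- function() {
  list(
    died_by_30 = list(
      type = "binary", control_mean = 0.009, ses_coef = -0.35,
      effect = list(base = 0.014, modifiers = NULL)),
    antidepressant_use = list(
      type = "binary", control_mean = 0.131, ses_coef = -0.20, censored = TRUE,
      effect = list(base = 0.010, modifiers = c(female = 0.070))),
    no_partnership = list(
      type = "binary", control_mean = 0.318, ses_coef = -0.30,
      effect = list(base = 0.040, modifiers = c(ses_index = -0.025))),
    basic_education_only = list(
      type = "binary", control_mean = 0.103, ses_coef = -0.50,
      effect = list(base = 0.005, modifiers = NULL)),
    unemployment_months_annualized = list(
      type = "zero_inflated_beta", control_mean = 1.02, ses_coef = -0.35,
      prob_any = 0.25, beta_a = 1,
      effect = list(base = 0.16, modifiers = NULL)),
    income_annual = list(
      type = "income", control_mean = 27453, ses_coef = 0.30,
      sdlog_resid = 0.45, censored = TRUE,
      effect = list(base = -1756, modifiers = NULL))
  )
}

default_region_probs <- function() {
  p <- c(0.30, 0.10, 0.09, 0.08, 0.07, 0.06, 0.05, 0.045, 0.04, 0.035,
         0.03, 0.025, 0.02, 0.02, 0.015, 0.01, 0.01)
  names(p) <- sprintf("R%02d", seq_along(p))
  p / sum(p)
}

default_ses_index_weights <- function()
  c(mother_edu = 1, father_edu = 1, household_earnings = 1, homeowner = 1,
    any_social_assistance = -1)

#' Configuration of the synthetic register cohort generator
#'
#' Builds a validated, fully calibrated generator configuration. Defaults
#' emulate the study design: 3048 treated children, a large stratified control
#' pool, covariate marginals matching the published full-population
#' descriptives, outcome margins matching the published group means
#' (control-group means of 0.9% mortality, 13.1% antidepressant use, 31.8%
#' unpartnered, 10.3% basic education only, 1.02 unemployment months/yr,
#' 27453 euros income), additive treatment effects on the probability/level
#' scale, a sex-modified antidepressant effect and a family-SES-modified
#' partnership effect, outcome censoring for the 1990 birth cohort, and
#' rounded, top-coded income.
#'
#' @param n_treated number of treated (exposed) persons assigned.
#' @param n_control_pool size of the untreated source pool.
#' @param seed default seed used by generation functions.
#' @param covariate_spec list of covariate specifications (see
#'   `default_covariate_spec` in the package source for the 37 drawn columns;
#'   `household_size` is derived).
#' @param treatment_model named coefficients (on standardized covariates) of
#'   the exponential-tilt sampling weights that select the treated.
#' @param outcome_models per-outcome model list: control-group calibration
#'   mean, a coefficient on the composite SES index, and the treatment effect
#'   (`base` plus named `modifiers` applied to raw covariate values;
#'   `ses_index` refers to the standardized composite index).
#' @param income_topcode,income_rounding disclosure-control processing of
#'   annual income (euros/year).
#' @param censor_cohorts birth years for which antidepressant and income
#'   outcomes are unobservable.
#' @param exclusion_rates named rates of the four exclusion flags, in the
#'   precedence order used by [apply_exclusions()].
#' @param region_probs named distribution over the 17 regions.
#' @param ses_index_weights signed weights of the standardized covariates
#'   entering the composite family-SES index.
#' @return a validated list of class `dgp_config`, including derived
#'   calibration constants (marginal moments, calibrated intercepts, the SES
#'   index normalization).
#' @export
dgp_config <- function(n_treated = 3048L,
                       n_control_pool = 120000L,
                       seed = 20240601L,
                       covariate_spec = default_covariate_spec(),
                       treatment_model = default_treatment_model(),
                       outcome_models = default_outcome_models(),
                       income_topcode = 150000,
                       income_rounding = 100,
                       censor_cohorts = 1990L,
                       exclusion_rates = c(pre7_diagnosis = 0.0025,
                                           missing_covariates = 0.008,
                                           death_before_18 = 0.002,
                                           emigration_before_18 = 0.0115),
                       region_probs = default_region_probs(),
                       ses_index_weights = default_ses_index_weights()) {
  if (n_treated < 1) stop("n_treated must be at least 1")
  if (income_topcode <= 0) stop("income_topcode must be positive")
  if (income_rounding <= 0) stop("income_rounding must be positive")
  nms <- vapply(covariate_spec, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicated covariate names")
  names(covariate_spec) <- nms
  all_names <- c(nms, derived_covariates(), "ses_index")

  check_refs <- function(ref_names, where) {
    bad <- setdiff(ref_names, all_names)
    if (length(bad))
      stop("unknown covariate in ", where, ": ", paste(bad, collapse = ", "))
  }
  check_refs(names(treatment_model), "treatment_model")
  check_refs(names(ses_index_weights), "ses_index_weights")
  for (on in names(outcome_models))
    check_refs(names(outcome_models[[on]]$effect$modifiers),
               paste0("outcome_models$", on))
  if (is.null(names(exclusion_rates)) ||
      !identical(names(exclusion_rates),
                 c("pre7_diagnosis", "missing_covariates", "death_before_18",
                   "emigration_before_18")))
    stop("exclusion_rates must be named in the standard precedence order")

  # derived calibration constants
  grid <- quad_grid()
  moments <- lapply(covariate_spec, cov_moments, grid = grid)

  wsi <- ses_index_weights
  gmat <- vapply(names(wsi), function(nm)
    (moments[[nm]]$g - moments[[nm]]$mean) / moments[[nm]]$sd * wsi[[nm]],
    numeric(length(grid$z)))
  vtot <- length(wsi)  # each standardized component has unit variance
  if (length(wsi) > 1) {
    for (j in seq_len(length(wsi) - 1)) for (k in (j + 1):length(wsi)) {
      cv <- sum(grid$w * gmat[, j] * gmat[, k]) -
        sum(grid$w * gmat[, j]) * sum(grid$w * gmat[, k])
      vtot <- vtot + 2 * cv
    }
  }
  ses_norm <- sqrt(vtot)

  structure(list(
    n_treated = as.integer(n_treated),
    n_control_pool = as.integer(n_control_pool),
    seed = as.integer(seed),
    covariate_spec = covariate_spec,
    treatment_model = treatment_model,
    outcome_models = outcome_models,
    income_topcode = income_topcode,
    income_rounding = income_rounding,
    censor_cohorts = as.integer(censor_cohorts),
    exclusion_rates = exclusion_rates,
    region_probs = region_probs,
    ses_index_weights = ses_index_weights,
    moments = moments,
    ses_norm = ses_norm
  ), class = "dgp_config")
}

#' Names of the modifier covariates
#'
#' The 38 columns offered to the forests as potential effect modifiers
#' (individual-, parent-, household- and postcode-level variables plus
#' remoteness and birth year). Region enters only as a matching stratum.
#'
#' @param config a [dgp_config()].
#' @return character vector of length 38.
#' @export
modifier_names <- function(config = dgp_config()) {
  c(names(config$covariate_spec), derived_covariates())
}

#' Write / read a generator configuration
#'
#' Serializes the user-settable configuration fields as YAML together with the
#' configuration hash; reading rebuilds (and revalidates) the config via
#' [dgp_config()].
#'
#' @param config a [dgp_config()].
#' @param path file path.
#' @return `read_dgp_config` returns a `dgp_config`.
#' @export
write_dgp_config <- function(config, path) {
  keep <- c("n_treated", "n_control_pool", "seed", "covariate_spec",
            "treatment_model", "outcome_models", "income_topcode",
            "income_rounding", "censor_cohorts", "exclusion_rates",
            "region_probs", "ses_index_weights")
  out <- config[keep]
  # named atomic vectors must be written as YAML maps to keep their names
  for (nm in c("treatment_model", "exclusion_rates", "region_probs",
               "ses_index_weights"))
    out[[nm]] <- as.list(out[[nm]])
  for (on in names(out$outcome_models)) {
    mods <- out$outcome_models[[on]]$effect$modifiers
    if (!is.null(mods)) out$outcome_models[[on]]$effect$modifiers <- as.list(mods)
  }
  out$config_hash <- config_hash(out)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_dgp_config
#' @export
read_dgp_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$config_hash <- NULL
  for (nm in c("treatment_model", "exclusion_rates", "region_probs",
               "ses_index_weights"))
    raw[[nm]] <- unlist(raw[[nm]])
  for (on in names(raw$outcome_models)) {
    mods <- raw$outcome_models[[on]]$effect$modifiers
    if (!is.null(mods))
      raw$outcome_models[[on]]$effect$modifiers <- unlist(mods)
  }
  do.call(dgp_config, raw)
}
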