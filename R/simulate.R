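# Synthetic register cohort: covariates, treatment assignment, outcomes.

standardize_cov <- function(cohort, config, name) {
  if (name == "ses_index") return(cohort$ses_index)  # already standardized
  mo <- config$moments[[name]]
  if (is.null(mo)) stop("unknown covariate: ", name)
  (cohort[[name]] - mo$mean) / mo$sd
}

ses_index_values <- function(cohort, config) {
  w <- config$ses_index_weights
  v <- numeric(nrow(cohort))
  for (nm in names(w)) v <- v + w[[nm]] * standardize_cov(cohort, config, nm)
  v / config$ses_norm
}

#' Generate covariates for a synthetic register cohort
#'
#' Draws the latent family-SES factor and all configured covariates (marginals
#' calibrated to the configured targets; cross-covariate correlation induced
#' only through the latent factor), the region and birth-year strata keys, the
#' derived household size, the composite `ses_index`, and mean-imputed father
#' covariates for rows with `missing_parent = 1`.
#'
#' @param config a [dgp_config()].
#' @param n number of persons.
#' @param seed integer seed (default `config$seed`); same seed, same table.
#' @return data.frame with `person_id`, `region`, the 38 modifier columns and
#'   `ses_index`.
#' @export
generate_covariates <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "dgp_config"), n >= 1)
  set.seed(derive_seed(seed, "covariates"))
  Z <- stats::rnorm(n)
  out <- list(person_id = seq_len(n),
              region = sample(names(config$region_probs), n, replace = TRUE,
                              prob = config$region_probs))
  for (sp in config$covariate_spec) {
    lam <- sp$loading
    mo <- config$moments[[sp$name]]
    x <- switch(sp$type,
      binary = stats::rbinom(n, 1, stats::plogis(mo$intercept + lam * Z)),
      normal = sp$mean + sp$sd * (lam * Z + sqrt(1 - lam^2) * stats::rnorm(n)),
      lognormal = sp$mean * exp(sp$sdlog * (lam * Z + sqrt(1 - lam^2) *
                    stats::rnorm(n)) - sp$sdlog^2 / 2),
      poisson = sp$shift + stats::rpois(n, exp(mo$intercept + lam * Z)),
      ordinal = findInterval(lam * Z + sqrt(1 - lam^2) * stats::rnorm(n),
                             mo$cuts) + 1L,
      logitnormal = stats::plogis(mo$intercept + sp$spread *
                      (lam * Z + sqrt(1 - lam^2) * stats::rnorm(n))),
      uniform_int = sample(sp$values, n, replace = TRUE),
      stop("unknown covariate type: ", sp$type))
    out[[sp$name]] <- x
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$household_size <- out$n_children + 2 - out$single_parent

  # reference-group (mean) imputation where the father is missing, keeping the
  # missing_parent indicator as the information carrier
  mp <- out$missing_parent == 1
  if (any(mp)) for (nm in father_imputed_covariates())
    out[[nm]][mp] <- config$moments[[nm]]$mean

  out$ses_index <- ses_index_values(out, config)
  out
}

flag_exclusions <- function(cohort, config, seed) {
  set.seed(derive_seed(seed, "exclusions"))
  n <- nrow(cohort)
  r <- config$exclusion_rates
  cohort$excl_pre7_diagnosis <- stats::rbinom(n, 1, r[["pre7_diagnosis"]])
  cohort$excl_missing_covariates <- stats::rbinom(n, 1, r[["missing_covariates"]])
  cohort$excl_death_before_18 <- stats::rbinom(n, 1, r[["death_before_18"]])
  cohort$excl_emigration_before_18 <- stats::rbinom(n, 1, r[["emigration_before_18"]])
  flags <- exclusion_flag_matrix(cohort)
  cohort$excluded_flag <- as.integer(rowSums(flags) > 0)
  first <- apply(flags, 1, function(z) if (any(z == 1)) which(z == 1)[1] else NA_integer_)
  cohort$exclusion_reason <- exclusion_reasons()[first]
  cohort
}

exclusion_reasons <- function()
  c("pre7_diagnosis", "missing_covariates", "death_before_18",
    "emigration_before_18")

exclusion_flag_matrix <- function(cohort) {
  cols <- paste0("excl_", exclusion_reasons())
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("exclusion flags missing from cohort: ", paste(missing_cols, collapse = ", "))
  as.matrix(cohort[cols])
}

#' Assign treatment by exponential-tilt sampling
#'
#' Selects exactly `config$n_treated` treated persons among the eligible
#' (non-excluded) rows by weighted sampling without replacement with weights
#' `exp(treatment_model . standardized covariates)`, reproducing the mild
#' covariate imbalances of the emulated case-identification step (more prior
#' hospital visits, household diabetes and siblings; fewer girls).
#'
#' @param cohort covariate table from [generate_covariates()].
#' @param config a [dgp_config()].
#' @param seed integer seed.
#' @return cohort with a `treated` column.
#' @export
assign_treatment <- function(cohort, config, seed = config$seed) {
  eligible <- if ("excluded_flag" %in% names(cohort))
    cohort$excluded_flag == 0 else rep(TRUE, nrow(cohort))
  n_el <- sum(eligible)
  if (config$n_treated > n_el)
    stop("n_treated exceeds the number of eligible persons")
  eta <- numeric(nrow(cohort))
  for (nm in names(config$treatment_model))
    eta <- eta + config$treatment_model[[nm]] * standardize_cov(cohort, config, nm)
  w <- exp(eta)
  set.seed(derive_seed(seed, "treatment"))
  # Efraimidis-Spirakis reservoir keys: top n_treated of log(U)/w
  key <- log(stats::runif(nrow(cohort))) / w
  key[!eligible] <- -Inf
  sel <- order(key, decreasing = TRUE)[seq_len(config$n_treated)]
  cohort$treated <- 0L
  cohort$treated[sel] <- 1L
  cohort
}

# Per-person treatment effect tau(x) implied by a configured outcome model:
# base effect plus modifier terms on raw covariate values (ses_index is the
# standardized composite). Additive on the probability / level scale.
tau_from_model <- function(cohort, config, model) {
  tau <- rep(model$effect$base, nrow(cohort))
  mods <- model$effect$modifiers
  for (nm in names(mods)) {
    val <- if (nm == "ses_index") cohort$ses_index else cohort[[nm]]
    tau <- tau + mods[[nm]] * val
  }
  tau
}

# Solve the intercept so that mean over `calib` rows of plogis(a + eta) hits
# the target exactly (sample-level calibration; leaves only draw noise).
calibrate_intercept <- function(eta, calib, target) {
  if (!any(calib)) stop("empty calibration group")
  e <- eta[calib]
  stats::uniroot(function(a) mean(stats::plogis(a + e)) - target,
                 c(-40, 20), tol = 1e-12)$root
}

#' Generate outcomes
#'
#' Mortality is drawn first (logistic baseline in the SES index plus an
#' additive treated-group probability shift); all other outcomes are drawn for
#' survivors only. Binary outcomes use logistic baselines with additive
#' probability-scale effects tau(x); annualized unemployment months follow a
#' zero-inflated scaled Beta on \[0, 12\] with the effect on the
#' any-unemployment probability; income is log-normal, scaled so the
#' control-survivor mean matches the calibration value, then shifted by the
#' treatment effect, rounded to `income_rounding` and capped at
#' `income_topcode`. Antidepressant and income outcomes are censored (set
#' missing) for the configured birth cohorts. Intercepts are calibrated on the
#' eligible control group so every configured control-group mean is reproduced
#' up to draw noise.
#'
#' @param cohort table with covariates and `treated`.
#' @param config a [dgp_config()].
#' @param seed integer seed.
#' @return cohort with the six outcome columns; calibrated model parameters are
#'   attached as attribute `outcome_params` (used by the potential-outcome
#'   test oracle).
#' @export
generate_outcomes <- function(cohort, config, seed = config$seed) {
  if (is.null(cohort$treated)) stop("assign treatment before generating outcomes")
  set.seed(derive_seed(seed, "outcomes"))
  n <- nrow(cohort)
  W <- cohort$treated
  ses <- cohort$ses_index
  eligible <- if ("excluded_flag" %in% names(cohort))
    cohort$excluded_flag == 0 else rep(TRUE, n)
  censored <- cohort$birth_year %in% config$censor_cohorts
  params <- list()
  clipped <- 0L

  draw_binary <- function(model, calib) {
    eta <- model$ses_coef * ses
    a <- calibrate_intercept(eta, calib, model$control_mean)
    p <- stats::plogis(a + eta) + W * tau_from_model(cohort, config, model)
    clipped <<- clipped + sum(p < 0 | p > 1)
    list(y = stats::rbinom(n, 1, clip(p, 0, 1)), intercept = a)
  }

  om <- config$outcome_models

  # mortality first
  mort <- draw_binary(om$died_by_30, eligible & W == 0)
  cohort$died_by_30 <- mort$y
  params$died_by_30 <- list(intercept = mort$intercept,
                            ses_coef = om$died_by_30$ses_coef)
  alive <- cohort$died_by_30 == 0

  blank <- function(y, keep) { y[!keep] <- NA; y }

  # antidepressants: survivors outside the censored cohorts
  m <- om$antidepressant_use
  keep <- alive & !censored
  ad <- draw_binary(m, eligible & W == 0 & keep)
  cohort$antidepressant_use <- blank(ad$y, keep)
  params$antidepressant_use <- list(intercept = ad$intercept, ses_coef = m$ses_coef)

  m <- om$no_partnership
  np <- draw_binary(m, eligible & W == 0 & alive)
  cohort$no_partnership <- blank(np$y, alive)
  params$no_partnership <- list(intercept = np$intercept, ses_coef = m$ses_coef)

  m <- om$basic_education_only
  be <- draw_binary(m, eligible & W == 0 & alive)
  cohort$basic_education_only <- blank(be$y, alive)
  params$basic_education_only <- list(intercept = be$intercept, ses_coef = m$ses_coef)

  # unemployment: zero-inflated scaled Beta
  m <- om$unemployment_months_annualized
  cmean <- m$control_mean / m$prob_any          # conditional months given any
  if (cmean <= 0 || cmean >= 12) stop("unemployment calibration out of range")
  beta_b <- 12 * m$beta_a / cmean - m$beta_a
  dpi <- m$effect$base / cmean                  # effect enters the zero part
  eta <- m$ses_coef * ses
  a <- calibrate_intercept(eta, eligible & W == 0 & alive, m$prob_any)
  ppi <- stats::plogis(a + eta) + W * dpi
  clipped <- clipped + sum(ppi < 0 | ppi > 1)
  any_u <- stats::rbinom(n, 1, clip(ppi, 0, 1))
  months <- any_u * 12 * stats::rbeta(n, m$beta_a, beta_b)
  cohort$unemployment_months_annualized <- blank(months, alive)
  params$unemployment_months_annualized <-
    list(intercept = a, ses_coef = m$ses_coef, dpi = dpi,
         beta_a = m$beta_a, beta_b = beta_b, cmean = cmean)

  # income: scaled log-normal, additive effect, rounding + top-coding
  m <- om$income_annual
  keep <- alive & !censored
  raw <- exp(m$ses_coef * ses + m$sdlog_resid * stats::rnorm(n))
  calib <- eligible & W == 0 & keep
  scale <- m$control_mean / mean(raw[calib])
  inc <- pmax(scale * raw + W * m$effect$base, 0)
  inc <- round(inc / config$income_rounding) * config$income_rounding
  inc <- pmin(inc, config$income_topcode)
  cohort$income_annual <- blank(inc, keep)
  params$income_annual <- list(scale = scale, ses_coef = m$ses_coef,
                               sdlog_resid = m$sdlog_resid)

  # isolated tail clippings are expected with unbounded covariates; warn only
  # when clipping is frequent enough to bias the calibration
  if (clipped > 1e-4 * n)
    warning(sprintf("%d outcome probabilities clipped to [0, 1]; configured effects exceed the baseline range", clipped))
  attr(cohort, "n_clipped") <- clipped
  attr(cohort, "outcome_params") <- params
  cohort
}

#' Simulate a full synthetic register cohort
#'
#' Orchestrates [generate_covariates()], exclusion flagging, [assign_treatment()]
#' and [generate_outcomes()] for a source pool of
#' `n_treated + n_control_pool` persons. The attached attributes record the
#' seed and configuration hash of the run.
#'
#' @param config a [dgp_config()].
#' @param seed integer master seed.
#' @return a cohort data.frame (one row per person).
#' @export
simulate_cohort <- function(config = dgp_config(), seed = config$seed) {
  n <- config$n_treated + config$n_control_pool
  cohort <- generate_covariates(config, n, seed)
  cohort <- flag_exclusions(cohort, config, seed)
  cohort <- assign_treatment(cohort, config, seed)
  cohort <- generate_outcomes(cohort, config, seed)
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "config_hash") <- config_hash(config[c(
    "n_treated", "n_control_pool", "treatment_model", "outcome_models",
    "income_topcode", "income_rounding", "censor_cohorts", "exclusion_rates")])
  cohort
}

#' Ground-truth conditional average treatment effect
#'
#' Returns tau(x_i) = E\[Y|W=1, x_i\] - E\[Y|W=0, x_i\] exactly as implied by
#' the configured outcome model (effects are additive on the probability /
#' level scale, so tau is the base effect plus modifier terms). Truth exists
#' even for censored outcomes.
#'
#' @param cohort a cohort table.
#' @param config the [dgp_config()] used to generate it.
#' @param outcome outcome name.
#' @return numeric vector, one effect per row.
#' @export
true_cate <- function(cohort, config, outcome) {
  model <- config$outcome_models[[outcome]]
  if (is.null(model)) stop("no configured model for outcome: ", outcome)
  tau_from_model(cohort, config, model)
}

outcome_names <- function()
  c("died_by_30", "antidepressant_use", "no_partnership",
    "basic_education_only", "unemployment_months_annualized", "income_annual")

table1_covariates <- function()
  c("any_social_assistance", "birth_year", "father_working", "homeowner",
    "hospital_visits_4_6", "household_assets", "household_earnings",
    "household_size", "mother_working", "single_parent", "female")

#' Calibration report
#'
#' Per-group means of the six outcomes and the headline covariates, formatted
#' for side-by-side comparison of the treated group, the matched control group
#' and the full population.
#'
#' @param cohort a cohort with outcomes.
#' @param matched optional matched sample from [match_controls()]; its control
#'   rows define the matched column.
#' @return data.frame with columns `variable`, `treated`, `matched`, `full`.
#' @export
calibration_report <- function(cohort, matched = NULL) {
  if (!any(cohort$treated == 1)) stop("no treated observations")
  grp_mean <- function(df, var) mean(df[[var]], na.rm = TRUE)
  groups <- list(treated = cohort[cohort$treated == 1, ],
                 matched = if (!is.null(matched))
                   matched[matched$treated == 0, ] else NULL,
                 full = cohort)
  vars <- c(outcome_names(), table1_covariates())
  out <- data.frame(variable = vars)
  for (g in names(groups)) {
    out[[g]] <- if (is.null(groups[[g]])) NA_real_
      else vapply(vars, grp_mean, numeric(1), df = groups[[g]])
  }
  out
}

#' Write / read a cohort table as CSV
#'
#' Plain CSV with a documented header (one row per person); the seed and
#' configuration hash attributes are stored in a `#`-comment first line.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hteforest cohort; seed=%s; config_hash=%s",
                     attr(cohort, "seed"), attr(cohort, "config_hash")), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
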