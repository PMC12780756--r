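# Heterogeneity workflow: pilot/final forest selection, cross-fitted CATE
# quartile ranking, per-quartile AIPW effects, covariate profiles and SMDs,
# plus the descriptive outcome table and group comparison tests.

#' Pilot and final forest with importance screening
#'
#' Trains a pilot causal forest on all covariates, keeps every covariate whose
#' split-frequency importance is at or above the mean importance, and trains
#' the final forest on the retained covariates only (same hyperparameters).
#'
#' @param centered a `centered_data` from [local_center()] (or a list with
#'   `y_tilde`, `w_tilde`, `ids`).
#' @param X covariate matrix aligned with `centered`.
#' @param params [forest_params()].
#' @param seed integer seed.
#' @return list: `selected` (covariate names), `pilot_importance`,
#'   `final_forest`, `pilot_forest`.
#' @export
pilot_final_fit <- function(centered, X, params = forest_params(), seed = 1L) {
  X <- check_X(X)
  if (ncol(X) < 2) stop("need at least 2 candidate covariates")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  pilot <- causal_forest(X, centered$y_tilde, centered$w_tilde, params,
                         seed = derive_seed(seed, "pilot"), ids = centered$ids)
  imp <- variable_importance(pilot)
  selected <- select_above_mean(imp)
  final <- causal_forest(X[, selected, drop = FALSE], centered$y_tilde,
                         centered$w_tilde, params,
                         seed = derive_seed(seed, "final"), ids = centered$ids)
  list(selected = selected, pilot_importance = imp,
       final_forest = final, pilot_forest = pilot)
}

#' Covariates at or above mean importance
#'
#' The pilot-forest screening rule: retain `{v : importance_v >= mean}`. A
#' zero importance vector (forest with no splits) retains everything, with a
#' warning.
#'
#' @param importance named importance vector.
#' @return character vector of retained names.
#' @export
select_above_mean <- function(importance) {
  if (is.null(names(importance)))
    names(importance) <- paste0("x", seq_along(importance))
  if (all(importance == 0)) {
    warning("pilot forest has no splits; retaining all covariates")
    return(names(importance))
  }
  names(importance)[importance >= mean(importance)]
}

#' Cross-fitted CATE ranks
#'
#' Randomly partitions the sample into K folds; for each fold the full
#' pipeline (local centering, pilot forest, covariate selection, final forest)
#' is trained on the other K-1 folds and used to predict CATEs, propensities
#' and outcome means for the held-out fold, so no person influences the forest
#' that ranks them. Pooled predictions are cut into quartile ranks
#' (1 = low effect group, 4 = high effect group) at the pooled empirical
#' quartiles; exact ties are broken deterministically by person id. Degenerate
#' constant predictions collapse to a single rank with a warning.
#'
#' @param X covariate matrix.
#' @param y outcome (no missing values; subset the analysis sample first).
#' @param w treatment indicator.
#' @param K number of folds (default 10).
#' @param params [forest_params()] for the pilot and final causal forests.
#' @param seed master seed (fold partition and per-fold forests use derived
#'   streams).
#' @param ids unique positive integer person ids.
#' @param n_ranks number of rank groups (default 4 quartiles).
#' @param nuisance_params [forest_params()] for the outcome-surface
#'   (centering) forest; defaults to `params`.
#' @param propensity_params [forest_params()] for the propensity forest;
#'   defaults to `nuisance_params`.
#' @return data.frame of class `rank_assignment`: `person_id`, `fold`,
#'   `tau_hat_crossfit`, `rank`, and cross-fitted `m_hat`, `e_hat`;
#'   per-fold selections are attached as attribute `fold_selected`.
#' @export
crossfit_ranks <- function(X, y, w, K = 10L, params = forest_params(),
                           seed = 1L, ids = NULL, n_ranks = 4L,
                           nuisance_params = params,
                           propensity_params = nuisance_params) {
  X <- check_X(X)
  n <- nrow(X)
  ids <- check_ids(ids, n)
  if (K > n / 4) stop("K too large for the sample (need n >= 4K)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  set.seed(derive_seed(seed, "folds"))
  fold <- sample(rep_len(seq_len(K), n))

  tau <- m_hat <- e_hat <- rep(NA_real_, n)
  fold_selected <- vector("list", K)
  for (k in seq_len(K)) {
    tr <- fold != k
    lc <- local_center(X[tr, , drop = FALSE], y[tr], w[tr], nuisance_params,
                       seed = derive_seed(seed, paste0("fold", k)),
                       ids = ids[tr], propensity_params = propensity_params)
    pf <- pilot_final_fit(lc$centered, X[tr, , drop = FALSE], params,
                          seed = derive_seed(seed, paste0("fold", k, "fit")))
    te <- !tr
    tau[te] <- predict(pf$final_forest,
                       X[te, pf$selected, drop = FALSE])
    m_hat[te] <- predict(lc$nuisance$m_forest, X[te, , drop = FALSE])
    e_hat[te] <- clip(predict(lc$nuisance$e_forest, X[te, , drop = FALSE]),
                      nuisance_params$clip_epsilon,
                      1 - nuisance_params$clip_epsilon)
    fold_selected[[k]] <- pf$selected
  }

  if (max(tau) - min(tau) <= 0) {
    warning("constant cross-fitted CATEs; assigning a single rank")
    rank <- rep(1L, n)
  } else {
    rank <- ntile_rank(tau, ids, n_ranks)
  }
  structure(data.frame(person_id = ids, fold = fold, tau_hat_crossfit = tau,
                       rank = rank, m_hat = m_hat, e_hat = e_hat),
            fold_selected = fold_selected,
            class = c("rank_assignment", "data.frame"))
}

#' Per-quartile AIPW effects
#'
#' Group-average AIPW effects for the CATE rank groups together with the
#' overall average effect on the treated.
#'
#' @param ranks a [crossfit_ranks()] table.
#' @param scores an [aipw_scores()] table for the same persons.
#' @return data.frame: one row per rank group plus an `ATT` row.
#' @export
quartile_effects <- function(ranks, scores) {
  if (!identical(as.integer(ranks$person_id), as.integer(scores$person_id)))
    stop("ranks and scores are not aligned by person_id")
  by_rank <- group_average_effect(scores, ranks$rank)
  att <- cbind(group = NA, average_effect(scores, "ATT"))
  rbind(by_rank, att)
}

#' Covariate means by CATE rank
#'
#' @param ranks a [crossfit_ranks()] table.
#' @param X covariate matrix aligned with `ranks`.
#' @return long data.frame: covariate, rank, mean, sd, n.
#' @export
covariate_profile <- function(ranks, X) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(ranks)) stop("X must be aligned with ranks")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- do.call(rbind, lapply(sort(unique(ranks$rank)), function(r) {
    sub <- X[ranks$rank == r, , drop = FALSE]
    data.frame(covariate = colnames(X), rank = r,
               mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
               n = nrow(sub), row.names = NULL)
  }))
  out
}

#' Standardized mean differences between the extreme rank groups
#'
#' For every covariate, SMD = (mean in rank 4 - mean in rank 1) /
#' sqrt((sd1^2 + sd4^2)/2): positive values are more prevalent in the
#' high-effect (most vulnerable) group. Zero pooled spread yields a missing
#' SMD.
#'
#' @param profile a [covariate_profile()] table containing ranks 1 and 4.
#' @return data.frame: covariate, mean_rank1, mean_rank4, pooled_sd, smd.
#' @export
smd_extremes <- function(profile) {
  lo <- profile[profile$rank == min(profile$rank), ]
  hi <- profile[profile$rank == max(profile$rank), ]
  stopifnot(identical(lo$covariate, hi$covariate))
  pooled <- sqrt((lo$sd^2 + hi$sd^2) / 2)
  smd <- ifelse(pooled > 0, (hi$mean - lo$mean) / pooled, NA_real_)
  data.frame(covariate = lo$covariate, mean_rank1 = lo$mean,
             mean_rank4 = hi$mean, pooled_sd = pooled, smd = smd)
}

# Analysis sample per outcome: mortality uses everyone; all other outcomes are
# conditional on surviving (and, for the censored outcomes, on an observable
# birth cohort) -- rows with a missing outcome are dropped.
analysis_sample <- function(cohort, outcome) {
  keep <- !is.na(cohort[[outcome]])
  cohort[keep, , drop = FALSE]
}

#' Outcome summary table
#'
#' Group means/fractions of the six outcomes for the treated and matched
#' control groups (censored and deceased rows excluded per outcome), in the
#' style of a descriptive outcomes table.
#'
#' @param matched a matched sample with outcomes.
#' @return data.frame: outcome, treated, control, n_treated, n_control.
#' @export
outcome_summary <- function(matched) {
  if (!any(matched$treated == 1) || !any(matched$treated == 0))
    stop("both treated and control rows are required")
  do.call(rbind, lapply(outcome_names(), function(on) {
    y <- matched[[on]]
    t <- y[matched$treated == 1 & !is.na(y)]
    c0 <- y[matched$treated == 0 & !is.na(y)]
    data.frame(outcome = on, treated = mean(t), control = mean(c0),
               n_treated = length(t), n_control = length(c0))
  }))
}

binary_outcomes <- function()
  c("died_by_30", "antidepressant_use", "no_partnership", "basic_education_only")

#' Group comparison tests
#'
#' Treated-versus-control tests per outcome: chi-square without continuity
#' correction for the dichotomous outcomes, Welch t-test for the continuous
#' ones.
#'
#' @param matched a matched sample with outcomes.
#' @return data.frame: outcome, test, p_value.
#' @export
group_comparison_tests <- function(matched) {
  do.call(rbind, lapply(outcome_names(), function(on) {
    y <- matched[[on]]
    ok <- !is.na(y)
    t1 <- y[ok & matched$treated == 1]
    c0 <- y[ok & matched$treated == 0]
    if (!length(t1) || !length(c0)) stop("empty group for outcome ", on)
    if (on %in% binary_outcomes()) {
      tab <- rbind(c(sum(t1), length(t1) - sum(t1)),
                   c(sum(c0), length(c0) - sum(c0)))
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      data.frame(outcome = on, test = "chi-square", p_value = p)
    } else {
      p <- stats::t.test(t1, c0)$p.value
      data.frame(outcome = on, test = "welch-t", p_value = p)
    }
  }))
}

#' Full heterogeneity analysis of one outcome
#'
#' Runs the complete workflow on a matched sample for one outcome: build the
#' per-outcome analysis sample, cross-fit CATE ranks (local centering + pilot
#' and final forests per fold), compute AIPW scores and rank-group effects,
#' and profile covariates across ranks with SMDs between the extreme groups.
#'
#' @param matched matched sample from [match_controls()].
#' @param outcome outcome name.
#' @param config the [dgp_config()] (supplies the modifier column names).
#' @param params [forest_params()] for the causal forests.
#' @param seed master seed.
#' @param K folds for cross-fitting.
#' @param nuisance_params [forest_params()] for the centering forests.
#' @param propensity_params [forest_params()] for the propensity forest.
#' @return list: `ranks`, `scores`, `effects`, `profile`, `smd`, `outcome`,
#'   `n`.
#' @export
analyze_outcome <- function(matched, outcome, config = dgp_config(),
                            params = forest_params(), seed = 1L, K = 10L,
                            nuisance_params = params,
                            propensity_params = nuisance_params) {
  rows <- analysis_sample(matched, outcome)
  X <- as.matrix(rows[, modifier_names(config), drop = FALSE])
  y <- rows[[outcome]]
  w <- rows$treated
  ranks <- crossfit_ranks(X, y, w, K = K, params = params, seed = seed,
                          ids = rows$person_id,
                          nuisance_params = nuisance_params,
                          propensity_params = propensity_params)
  scores <- aipw_scores(y, w, ranks$m_hat, ranks$e_hat,
                        ranks$tau_hat_crossfit, ids = rows$person_id)
  effects <- quartile_effects(ranks, scores)
  profile <- covariate_profile(ranks, X)
  smd <- smd_extremes(profile)
  list(outcome = outcome, n = nrow(rows), ranks = ranks, scores = scores,
       effects = effects, profile = profile, smd = smd)
}

#' Run the whole study pipeline
#'
#' Simulate (or take) a cohort, apply exclusions, match controls, and analyze
#' every outcome. Returns the per-outcome analysis lists plus the descriptive
#' tables.
#'
#' @param config a [dgp_config()].
#' @param seed master seed.
#' @param params [forest_params()].
#' @param outcomes outcomes to analyze (default all six).
#' @param cohort optional pre-simulated cohort.
#' @param K folds.
#' @return list: `matched`, `exclusions`, `table2`, `tests`, `analyses`.
#' @export
run_analysis <- function(config = dgp_config(), seed = config$seed,
                         params = forest_params(),
                         outcomes = outcome_names(), cohort = NULL, K = 10L) {
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed)
  ex <- apply_exclusions(cohort)
  matched <- match_controls(ex$cohort, seed = derive_seed(seed, "match"))
  analyses <- lapply(outcomes, function(on)
    analyze_outcome(matched, on, config, params,
                    seed = derive_seed(seed, paste0("analyze:", on)), K = K))
  names(analyses) <- outcomes
  list(matched = matched, exclusions = ex$counts,
       table2 = outcome_summary(matched),
       tests = group_comparison_tests(matched), analyses = analyses)
}
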