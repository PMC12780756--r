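# Local centering: out-of-bag nuisance fits and orthogonalized residuals.

#' Locally center outcome and treatment
#'
#' Fits honest out-of-bag regression forests for the outcome surface
#' m(x) = E\[Y|X=x\] and the propensity e(x) = E\[W|X=x\], clips the propensity
#' to \[eps, 1-eps\], and returns the orthogonalized residuals
#' \eqn{\tilde Y_i = Y_i - \hat m^{(-i)}(X_i)},
#' \eqn{\tilde W_i = W_i - \hat e^{(-i)}(X_i)} used by the causal forest
#' (residual-on-residual regressions). Rows with missing outcomes must be
#' dropped by the caller first.
#'
#' @param X covariate matrix (no missing values).
#' @param y numeric outcome.
#' @param w binary treatment indicator.
#' @param params [forest_params()] for the outcome forest; `clip_epsilon`
#'   bounds the propensity.
#' @param seed integer seed (nuisance forests use derived sub-streams).
#' @param ids optional unique positive integer ids.
#' @param propensity_params [forest_params()] for the propensity forest
#'   (default `params`). In matched or randomized designs the propensity is
#'   near-constant, so a coarser forest (larger minimum node size) estimates
#'   it with less noise.
#' @return list with `centered` (class `centered_data`: `y_tilde`, `w_tilde`,
#'   `ids`) and `nuisance` (class `nuisance_fit`: `m_hat`, `e_hat`, the two
#'   forests, `clip_epsilon`).
#' @export
local_center <- function(X, y, w, params = forest_params(), seed = 1L,
                         ids = NULL, propensity_params = params) {
  X <- check_X(X)
  n <- nrow(X)
  ids <- check_ids(ids, n)
  if (anyNA(y) || anyNA(w)) stop("y and w must not contain missing values")
  if (length(unique(w)) < 2) stop("propensity degenerate: treatment is constant")
  m_forest <- regression_forest(X, y, params, seed = derive_seed(seed, "m_hat"),
                                ids = ids)
  e_forest <- regression_forest(X, w, propensity_params,
                                seed = derive_seed(seed, "e_hat"), ids = ids)
  eps <- params$clip_epsilon
  m_hat <- m_forest$oob_predictions
  e_hat <- clip(e_forest$oob_predictions, eps, 1 - eps)
  centered <- structure(list(y_tilde = y - m_hat, w_tilde = w - e_hat,
                             ids = ids), class = "centered_data")
  nuisance <- structure(list(m_hat = m_hat, e_hat = e_hat,
                             m_forest = m_forest, e_forest = e_forest,
                             clip_epsilon = eps, ids = ids),
                        class = "nuisance_fit")
  if (any(!is.finite(centered$y_tilde)) || any(!is.finite(centered$w_tilde)))
    stop("non-finite residuals after centering")
  list(centered = centered, nuisance = nuisance)
}

#' Serialize a nuisance fit
#'
#' @param nuisance a `nuisance_fit`.
#' @param path CSV path (columns id, m_hat, e_hat).
#' @export
write_nuisance <- function(nuisance, path) {
  utils::write.csv(data.frame(id = nuisance$ids, m_hat = nuisance$m_hat,
                              e_hat = nuisance$e_hat),
                   path, row.names = FALSE)
  invisible(path)
}
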