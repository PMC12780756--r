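# Honest subsampled forests: user-facing wrappers around the C++ engine.

#' Forest hyperparameters
#'
#' Fixed, overridable defaults shared by the regression (nuisance) and causal
#' forests. Automatic cross-validated tuning is deliberately not provided; these
#' are documented defaults in the spirit of generalized random forests.
#'
#' @param num_trees number of trees.
#' @param sample_fraction fraction of rows subsampled (without replacement) per
#'   tree.
#' @param honesty_fraction fraction of each tree's subsample used for choosing
#'   splits (the J1 half); the rest (J2) populates leaf estimates.
#' @param min_node_size minimum rows per child, enforced on both honest halves.
#' @param mtry candidate covariates per split; default `ceiling(sqrt(p))`,
#'   resolved at fit time when `NULL`.
#' @param clip_epsilon propensity clipping bound used by [local_center()].
#' @return a list of class `forest_params`.
#' @export
forest_params <- function(num_trees = 500L, sample_fraction = 0.5,
                          honesty_fraction = 0.5, min_node_size = 5L,
                          mtry = NULL, clip_epsilon = 0.01) {
  stopifnot(num_trees >= 1, sample_fraction > 0, sample_fraction <= 1,
            honesty_fraction > 0, honesty_fraction < 1, min_node_size >= 1,
            clip_epsilon > 0, clip_epsilon < 0.5)
  structure(list(num_trees = as.integer(num_trees),
                 sample_fraction = sample_fraction,
                 honesty_fraction = honesty_fraction,
                 min_node_size = as.integer(min_node_size),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 clip_epsilon = clip_epsilon),
            class = "forest_params")
}

resolve_mtry <- function(params, p) {
  if (is.null(params$mtry)) as.integer(ceiling(sqrt(p))) else min(params$mtry, p)
}

check_X <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("covariate matrix must be finite with no missing values")
  X
}

check_ids <- function(ids, n) {
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (length(ids) != n || anyNA(ids) || any(ids < 1) || anyDuplicated(ids))
    stop("ids must be unique positive integers, one per row")
  ids
}

fit_forest <- function(X, target, w_tilde, causal, params, seed, ids) {
  X <- check_X(X)
  n <- nrow(X)
  ids <- check_ids(ids, n)
  if (length(target) != n) stop("target length does not match X")
  mtry <- resolve_mtry(params, ncol(X))
  ptr <- cpp_fit_forest(X, as.double(target),
                        if (causal) as.double(w_tilde) else numeric(0),
                        causal, ids, params$num_trees, params$sample_fraction,
                        params$honesty_fraction, params$min_node_size, mtry,
                        as.double(seed %% 2^31))
  structure(list(ptr = ptr, params = params, mtry = mtry, seed = seed,
                 n = n, p = ncol(X), ids = ids,
                 covariate_names = colnames(X)),
            class = if (causal) c("causal_forest", "hte_forest")
                    else c("regression_forest", "hte_forest"))
}

#' Honest regression forest with out-of-bag predictions
#'
#' Variance-reduction splitting on the splitting half of each tree's subsample,
#' leaf means from the estimation half. Out-of-bag predictions for row i use
#' only trees whose subsample excludes i. Used to fit the nuisance surfaces
#' m(x) = E\[Y|X=x\] and e(x) = E\[W|X=x\] for local centering.
#'
#' @param X numeric covariate matrix (no missing values).
#' @param y numeric target.
#' @param params a [forest_params()] object.
#' @param seed integer seed; fully determines the fit.
#' @param ids optional unique positive integer row ids (default `1:n`); all
#'   internal randomness is keyed on ids, so predictions are invariant to row
#'   permutation.
#' @return object of class `regression_forest` with element `oob_predictions`.
#' @export
regression_forest <- function(X, y, params = forest_params(), seed = 1L,
                              ids = NULL) {
  fit <- fit_forest(X, y, NULL, causal = FALSE, params = params,
                    seed = seed, ids = ids)
  fit$oob_predictions <- cpp_rf_predict_oob(fit$ptr)
  fit
}

#' Honest causal forest on locally centered data
#'
#' The core estimator: trees are grown on residualized data (`y_tilde`,
#' `w_tilde` from [local_center()]) with gradient pseudo-outcome splitting that
#' maximizes differences in estimated CATEs across children while weighting by
#' child sample sizes. CATE predictions are forest-weighted
#' residual-on-residual regressions
#' \deqn{\hat\tau(x) = \sum_i \alpha_i(x)\tilde W_i \tilde Y_i /
#'       \sum_i \alpha_i(x) \tilde W_i^2,}
#' with adaptive weights \eqn{\alpha_i(x)} given by estimation-leaf
#' co-membership. Predictions for training rows are out-of-bag.
#'
#' @param X covariate (modifier) matrix.
#' @param y_tilde centered outcome residuals.
#' @param w_tilde centered treatment residuals.
#' @inheritParams regression_forest
#' @return object of class `causal_forest`.
#' @export
causal_forest <- function(X, y_tilde, w_tilde, params = forest_params(),
                          seed = 1L, ids = NULL) {
  if (length(w_tilde) != length(y_tilde)) stop("y_tilde and w_tilde lengths differ")
  fit_forest(X, y_tilde, w_tilde, causal = TRUE, params = params,
             seed = seed, ids = ids)
}

#' @export
predict.regression_forest <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$oob_predictions)
  cpp_rf_predict(object$ptr, check_X(newdata))
}

#' Predict CATEs from a causal forest
#'
#' With `newdata = NULL`, returns out-of-bag CATEs for the training rows.
#' Queries where the forest-weighted residual treatment variance is zero fall
#' back to the forest-wide residual-on-residual slope; the number of such
#' queries is reported via the `n_fallback` attribute (and a warning).
#'
#' @param object a [causal_forest()].
#' @param newdata optional covariate matrix of query points.
#' @param ... unused.
#' @return numeric vector of CATEs with attribute `n_fallback`.
#' @export
predict.causal_forest <- function(object, newdata = NULL, ...) {
  res <- if (is.null(newdata)) cpp_cf_predict_oob(object$ptr)
         else cpp_cf_predict(object$ptr, check_X(newdata))
  tau <- res$tau
  nf <- sum(res$fallback)
  if (nf > 0)
    warning(sprintf("%d quer%s had zero weighted treatment variance; used forest-wide estimate",
                    nf, if (nf == 1) "y" else "ies"))
  attr(tau, "n_fallback") <- nf
  tau
}

#' Adaptive forest weights
#'
#' The data-adaptive kernel \eqn{\alpha_i(x)}: over the counted trees, each
#' estimation-half member of the leaf containing x receives weight
#' 1 / (number of counted trees x leaf size). For training-row queries
#' (`oob = TRUE` with `newdata = NULL`), only trees whose subsample excludes
#' the row are counted.
#'
#' @param forest a fitted forest.
#' @param newdata query covariate matrix; `NULL` for the training rows.
#' @param oob apply the out-of-bag rule to training-row queries.
#' @return matrix (queries x training rows) of nonnegative weights, each row
#'   summing to 1.
#' @export
forest_weights <- function(forest, newdata = NULL, oob = TRUE) {
  if (is.null(newdata)) {
    Xq <- matrix(0, forest$n, forest$p)
    # re-extract training X by predicting is not possible; keep a copy in C++?
    stop("supply newdata explicitly, or use forest_weights_oob() for training rows")
  }
  Xq <- check_X(newdata)
  cpp_forest_weights(forest$ptr, Xq, rep(-1L, nrow(Xq)))
}

#' @rdname forest_weights
#' @param query_rows integer indices of training rows to use as out-of-bag
#'   queries.
#' @param X the training covariate matrix (as passed to the fit).
#' @export
forest_weights_oob <- function(forest, X, query_rows) {
  X <- check_X(X)
  stopifnot(nrow(X) == forest$n)
  cpp_forest_weights(forest$ptr, X[query_rows, , drop = FALSE],
                     as.integer(query_rows) - 1L)
}

#' Node pseudo-outcomes for gradient splitting
#'
#' Within a node, the residual-on-residual solution is
#' \eqn{\tau_P = \sum \tilde W_i\tilde Y_i / \sum \tilde W_i^2}; with
#' \eqn{A_P = \mathrm{mean}(\tilde W_i^2)} the pseudo-outcomes are
#' \eqn{\rho_i = \tilde W_i(\tilde Y_i - \tilde W_i\tau_P)/A_P}, which sum to
#' zero exactly.
#'
#' @param w_tilde,y_tilde centered treatment / outcome residuals of the node's
#'   splitting-half rows.
#' @return list with `tau`, `A` and `rho`.
#' @export
node_pseudo_outcomes <- function(w_tilde, y_tilde) {
  stopifnot(length(w_tilde) == length(y_tilde), length(w_tilde) >= 2)
  cpp_node_pseudo_outcomes(as.double(w_tilde), as.double(y_tilde))
}

#' Best axis-aligned split of a node
#'
#' Maximizes \eqn{\Delta = (\sum_L\rho)^2/n_L + (\sum_R\rho)^2/n_R} over the
#' candidate covariates and all midpoints between consecutive distinct
#' splitting-half values, requiring at least `min_node` rows per child in both
#' honest halves. Ties are broken toward the lowest covariate index, then the
#' lowest threshold. This is the single-node version of the rule used
#' internally by the tree grower.
#'
#' @param X1 splitting-half covariate matrix.
#' @param rho splitting-half pseudo-outcomes.
#' @param X2 estimation-half covariate matrix.
#' @param min_node minimum child size in each half.
#' @param candidates 1-based candidate covariate indices (default all).
#' @return list with `var`, `threshold`, `delta`, or `NULL` when no admissible
#'   split exists.
#' @export
best_split <- function(X1, rho, X2, min_node = 5L, candidates = NULL) {
  X1 <- check_X(X1); X2 <- check_X(X2)
  if (is.null(candidates)) candidates <- seq_len(ncol(X1))
  if (length(rho) != nrow(X1)) stop("rho length must match nrow(X1)")
  cpp_best_split(X1, as.double(rho), X2, as.integer(min_node),
                 as.integer(candidates))
}

#' Split-frequency variable importance
#'
#' The weighted number of times each covariate is used to make a split:
#' \eqn{\mathrm{imp}_v = \sum_{d\le D} d^{-k}\,
#' \frac{\#\{\text{splits on } v \text{ at depth } d\}}
#'      {\#\{\text{splits at depth } d\}}},
#' normalized to sum to one (a zero vector when the forest has no splits).
#'
#' @param forest a fitted forest.
#' @param decay depth decay exponent k.
#' @param max_depth deepest level D counted.
#' @return named numeric vector over covariates.
#' @export
variable_importance <- function(forest, decay = 2, max_depth = 4L) {
  imp <- cpp_variable_importance(forest$ptr, decay, as.integer(max_depth))
  names(imp) <- forest$covariate_names
  imp
}

#' Inspectable forest structure
#'
#' Returns the forest as plain R data (per tree: split table, honest halves and
#' estimation-leaf membership by person id), suitable for JSON export with
#' [jsonlite::toJSON()] and for structural regression tests.
#'
#' @param forest a fitted forest.
#' @return list of trees.
#' @export
forest_structure <- function(forest) {
  structure(list(params = forest$params, mtry = forest$mtry, seed = forest$seed,
                 causal = inherits(forest, "causal_forest"),
                 trees = cpp_forest_structure(forest$ptr)),
            class = "forest_structure")
}

#' @export
print.hte_forest <- function(x, ...) {
  info <- cpp_forest_info(x$ptr)
  cat(sprintf("%s: %d trees, n = %d, p = %d, min node = %d, mtry = %d\n",
              if (info$causal) "Honest causal forest" else "Honest regression forest",
              info$num_trees, info$n, info$p, x$params$min_node_size, x$mtry))
  invisible(x)
}
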