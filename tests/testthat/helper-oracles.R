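# Independent oracles used across the suite. These deliberately re-derive the
# quantities by brute force / first principles and never call the fast paths
# they are checking.

# Exhaustive split search: every candidate covariate, every midpoint between
# consecutive distinct splitting-half values, both-halves min-node constraint,
# first strict improvement wins (lowest covariate index, lowest threshold).
oracle_best_split <- function(X1, rho, X2, min_node,
                              candidates = seq_len(ncol(X1))) {
  best <- NULL
  total <- sum(rho)
  for (v in sort(candidates)) {
    xs <- sort(unique(X1[, v]))
    if (length(xs) < 2) next
    thrs <- xs[-length(xs)] + diff(xs) / 2
    for (thr in thrs) {
      left <- X1[, v] <= thr
      nl1 <- sum(left); nr1 <- nrow(X1) - nl1
      nl2 <- sum(X2[, v] <= thr); nr2 <- nrow(X2) - nl2
      if (min(nl1, nr1, nl2, nr2) < min_node) next
      sl <- sum(rho[left]); sr <- total - sl
      delta <- sl^2 / nl1 + sr^2 / nr1
      if (is.null(best) || delta > best$delta)
        best <- list(var = v, threshold = thr, delta = delta)
    }
  }
  if (!is.null(best) && best$delta <= 0) best <- NULL
  best
}

# Route a query through one exported tree structure; returns the leaf node row.
route_tree <- function(nodes, x) {
  i <- 1L
  while (!is.na(nodes$var[i]))
    i <- if (x[nodes$var[i]] <= nodes$threshold[i]) nodes$left[i] else nodes$right[i]
  i
}

# Reference forest weights alpha_i(x) computed in R from the exported
# structure (by person id). exclude_id applies the out-of-bag rule.
ref_forest_weights <- function(fs, x, all_ids, exclude_id = NULL) {
  counted <- vapply(fs$trees, function(tr) {
    is.null(exclude_id) || !(exclude_id %in% c(tr$j1, tr$j2))
  }, logical(1))
  used <- sum(counted)
  stopifnot(used > 0)
  w <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (tr in fs$trees[counted]) {
    leaf <- route_tree(tr$nodes, x)
    mem <- tr$leaf_members[[leaf]]
    if (length(mem) == 0) next
    w[as.character(mem)] <- w[as.character(mem)] + 1 / (used * length(mem))
  }
  w
}

# Reference CATE from reference weights and the training residuals.
ref_predict_cate <- function(fs, x, ids, y_tilde, w_tilde, exclude_id = NULL) {
  a <- ref_forest_weights(fs, x, ids, exclude_id)
  a <- a[as.character(ids)]
  sum(a * w_tilde * y_tilde) / sum(a * w_tilde^2)
}

# Simple smooth-heterogeneity testbed: randomized treatment, linear baseline,
# configurable tau(x).
make_cf_data <- function(n, p = 5, tau_fun = function(X) rep(2, nrow(X)),
                         prop = 0.5, noise = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  w <- stats::rbinom(n, 1, prop)
  tau <- tau_fun(X)
  y <- X[, 1] + tau * w + noise * stats::rnorm(n)
  list(X = X, w = w, y = y, tau = tau)
}

fast_params <- function(num_trees = 100, min_node_size = 10, ...)
  forest_params(num_trees = num_trees, min_node_size = min_node_size, ...)

small_config <- function(n_treated = 150, n_control_pool = 6000, ...)
  dgp_config(n_treated = n_treated, n_control_pool = n_control_pool, ...)
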