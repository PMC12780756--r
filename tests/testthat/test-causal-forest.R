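# Core honest causal forest machinery: pseudo-outcomes, split search, honesty,
# forest weights, CATE prediction, importance, determinism.

test_that("node pseudo-outcomes match hand arithmetic and sum to zero", {
  # perfectly homogeneous node: tau = 1, all rho = 0
  r <- node_pseudo_outcomes(c(0.5, -0.5), c(0.5, -0.5))
  expect_equal(r$tau, 1)
  expect_equal(r$rho, c(0, 0))

  # 4-row hand example: sum(w~ y~) = 0.5, sum(w~^2) = 1 => tau = 0.5,
  # A = 0.25, rho_i = w~_i (y~_i - w~_i/2) / 0.25
  r <- node_pseudo_outcomes(c(0.5, 0.5, -0.5, -0.5), c(1, 0, 0, 0))
  expect_equal(r$tau, 0.5)
  expect_equal(r$A, 0.25)
  expect_equal(r$rho, c(1.5, -0.5, -0.5, -0.5))

  # algebraic identity on random nodes
  set.seed(4)
  for (i in 1:20) {
    w <- rnorm(50); y <- rnorm(50)
    expect_lt(abs(sum(node_pseudo_outcomes(w, y)$rho)), 1e-10)
  }

  expect_error(node_pseudo_outcomes(c(0, 0), c(1, 2)),
               "no residual treatment variation")
})

test_that("best_split agrees with exhaustive brute-force search", {
  set.seed(7)
  checked <- 0
  for (i in 1:60) {
    n1 <- sample(10:80, 1)
    n2 <- sample(10:80, 1)
    p <- sample(1:5, 1)
    X1 <- matrix(rnorm(n1 * p), n1, p)
    X2 <- matrix(rnorm(n2 * p), n2, p)
    rho <- node_pseudo_outcomes(rnorm(n1), rnorm(n1))$rho
    mn <- sample(2:6, 1)
    got <- best_split(X1, rho, X2, min_node = mn)
    want <- oracle_best_split(X1, rho, X2, min_node = mn)
    if (is.null(want)) {
      expect_null(got)
    } else {
      checked <- checked + 1
      expect_equal(got$var, want$var)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$delta, want$delta, tolerance = 1e-10)
    }
  }
  expect_gt(checked, 30)
})

test_that("best_split respects the size guard", {
  set.seed(1)
  X1 <- matrix(rnorm(8), 8, 1)
  X2 <- matrix(rnorm(8), 8, 1)
  rho <- rnorm(8)
  expect_null(best_split(X1, rho, X2, min_node = 5))   # node < 2 * min_node
  # identical covariate values admit no threshold
  expect_null(best_split(matrix(1, 20, 1), rnorm(20), matrix(1, 20, 1),
                         min_node = 2))
})

test_that("degenerate inputs give single-leaf trees", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n), n, 1)
  yt <- rnorm(n); wt <- rbinom(n, 1, 0.5) - 0.5
  # min node size >= |J1| forbids any split
  cf <- causal_forest(X, yt, wt, forest_params(num_trees = 5,
                                               min_node_size = 40), seed = 1)
  fs <- forest_structure(cf)
  expect_true(all(vapply(fs$trees, function(t) nrow(t$nodes) == 1, TRUE)))

  # identical covariate rows: no admissible threshold
  cf2 <- causal_forest(matrix(1, n, 1), yt, wt,
                       forest_params(num_trees = 5, min_node_size = 2), seed = 1)
  fs2 <- forest_structure(cf2)
  expect_true(all(vapply(fs2$trees, function(t) nrow(t$nodes) == 1, TRUE)))
})

test_that("strong step heterogeneity is found at the root on the true modifier", {
  d <- make_cf_data(600, p = 3, tau_fun = function(X) ifelse(X[, 1] > 0, 1, -1),
                    noise = 0.1, seed = 11)
  lc <- local_center(d$X, d$y, d$w, fast_params(100, 10), seed = 3)
  cf <- causal_forest(d$X, lc$centered$y_tilde, lc$centered$w_tilde,
                      forest_params(num_trees = 200, min_node_size = 10,
                                    mtry = 3), seed = 5)
  fs <- forest_structure(cf)
  roots <- vapply(fs$trees, function(t) t$nodes$var[1], 1L)
  thrs <- vapply(fs$trees, function(t) t$nodes$threshold[1], 1.0)
  expect_gt(mean(roots == 1, na.rm = TRUE), 0.9)
  expect_lt(median(abs(thrs[roots == 1])), 0.25)
})

test_that("forest weights match hand examples and the R reference", {
  # hand example: two trees whose leaves at x contain ids {1} and {1, 2}
  fake <- list(trees = list(
    list(nodes = data.frame(var = NA_integer_, threshold = NA_real_,
                            left = NA_integer_, right = NA_integer_, depth = 1),
         leaf_members = list(c(1L)), j1 = 3L, j2 = 1L),
    list(nodes = data.frame(var = NA_integer_, threshold = NA_real_,
                            left = NA_integer_, right = NA_integer_, depth = 1),
         leaf_members = list(c(1L, 2L)), j1 = 4L, j2 = c(1L, 2L))))
  a <- ref_forest_weights(fake, x = 0, all_ids = 1:4)
  expect_equal(unname(a), c(0.75, 0.25, 0, 0))

  # single tree, leaf holding {3, 5}
  fake1 <- list(trees = fake$trees[2])
  fake1$trees[[1]]$leaf_members <- list(c(3L, 5L))
  a1 <- ref_forest_weights(fake1, x = 0, all_ids = 1:5)
  expect_equal(unname(a1), c(0, 0, 0.5, 0, 0.5))

  # fitted forest: C++ weights == R reference from the exported structure
  d <- make_cf_data(150, p = 3, seed = 21)
  lc <- local_center(d$X, d$y, d$w, fast_params(60, 8), seed = 2)
  cf <- causal_forest(d$X, lc$centered$y_tilde, lc$centered$w_tilde,
                      fast_params(30, 8), seed = 9)
  fs <- forest_structure(cf)
  q <- matrix(rnorm(3 * 3), 3, 3)
  W <- forest_weights(cf, q)
  for (j in 1:3) {
    ref <- ref_forest_weights(fs, q[j, ], all_ids = 1:150)
    expect_equal(unname(W[j, ]), unname(ref[as.character(1:150)]),
                 tolerance = 1e-12)
  }
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-12)

  # OOB rule: excluded trees are the in-bag ones
  Woob <- forest_weights_oob(cf, d$X, 1:2)
  for (j in 1:2) {
    ref <- ref_forest_weights(fs, d$X[j, ], all_ids = 1:150, exclude_id = j)
    expect_equal(unname(Woob[j, ]), unname(ref[as.character(1:150)]),
                 tolerance = 1e-12)
    expect_equal(Woob[j, j], 0)   # own row never contributes out of bag
  }
})

test_that("CATE prediction is the forest-weighted residual regression", {
  # exact linear relation: y~ = c w~ => tau(x) = c everywhere
  set.seed(31)
  n <- 300
  X <- matrix(rnorm(n * 2), n, 2)
  wt <- rbinom(n, 1, 0.5) - 0.5
  cf <- causal_forest(X, 3 * wt, wt, fast_params(50, 10), seed = 2)
  expect_equal(unname(predict(cf, X[1:20, ])), rep(3, 20), tolerance = 1e-10,
               ignore_attr = TRUE)

  # against the R reference on new queries
  d <- make_cf_data(200, p = 3, seed = 5)
  lc <- local_center(d$X, d$y, d$w, fast_params(60, 8), seed = 4)
  yt <- lc$centered$y_tilde; wt <- lc$centered$w_tilde
  cf2 <- causal_forest(d$X, yt, wt, fast_params(40, 8), seed = 6)
  fs <- forest_structure(cf2)
  q <- matrix(rnorm(6), 2, 3)
  got <- predict(cf2, q)
  for (j in 1:2)
    expect_equal(got[j], ref_predict_cate(fs, q[j, ], 1:200, yt, wt),
                 tolerance = 1e-10)
})

test_that("constant-effect DGP is recovered without bias", {
  d <- make_cf_data(1200, p = 4, tau_fun = function(X) rep(2, nrow(X)),
                    seed = 17)
  lc <- local_center(d$X, d$y, d$w, fast_params(200, 10), seed = 8)
  cf <- causal_forest(d$X, lc$centered$y_tilde, lc$centered$w_tilde,
                      fast_params(200, 10), seed = 9)
  tau <- predict(cf)
  expect_lt(abs(mean(tau) - 2), 0.2)
})

test_that("predictions are deterministic in the seed and invariant to row order", {
  d <- make_cf_data(250, p = 3, seed = 13)
  lc <- local_center(d$X, d$y, d$w, fast_params(60, 8), seed = 1)
  yt <- lc$centered$y_tilde; wt <- lc$centered$w_tilde
  cf_a <- causal_forest(d$X, yt, wt, fast_params(50, 8), seed = 77)
  cf_b <- causal_forest(d$X, yt, wt, fast_params(50, 8), seed = 77)
  expect_identical(predict(cf_a), predict(cf_b))
  cf_c <- causal_forest(d$X, yt, wt, fast_params(50, 8), seed = 78)
  expect_false(identical(predict(cf_a), predict(cf_c)))

  # permute rows, keep ids: every person's OOB prediction is unchanged
  perm <- sample(250)
  cf_p <- causal_forest(d$X[perm, ], yt[perm], wt[perm], fast_params(50, 8),
                        seed = 77, ids = perm)
  expect_equal(as.numeric(predict(cf_p))[order(perm)],
               as.numeric(predict(cf_a)), tolerance = 1e-12)
})

test_that("tree structure is honest: estimation-half outcomes never shape splits", {
  # single-tree forests: scramble the residuals of that tree's own J2
  # (estimation) half and refit; the split structure must be unchanged because
  # splits use J1 outcomes only (J2 enters solely through covariate counts)
  d <- make_cf_data(300, p = 3, seed = 23)
  lc <- local_center(d$X, d$y, d$w, fast_params(60, 8), seed = 5)
  yt <- lc$centered$y_tilde; wt <- lc$centered$w_tilde
  for (s in 1:6) {
    cf <- causal_forest(d$X, yt, wt, fast_params(1, 8), seed = s)
    fs <- forest_structure(cf)
    j2_ids <- fs$trees[[1]]$j2
    set.seed(99 + s)
    yt2 <- yt
    yt2[j2_ids] <- yt[j2_ids] + rnorm(length(j2_ids), sd = 5)
    cf2 <- causal_forest(d$X, yt2, wt, fast_params(1, 8), seed = s)
    fs2 <- forest_structure(cf2)
    expect_identical(fs$trees[[1]]$j1, fs2$trees[[1]]$j1)
    expect_identical(fs$trees[[1]]$nodes, fs2$trees[[1]]$nodes)
    # leaf estimates, by contrast, do respond to the J2 outcomes
    expect_false(identical(predict(cf, d$X[1:20, ]),
                           predict(cf2, d$X[1:20, ])))
  }
})

test_that("variable importance reflects split frequency with depth decay", {
  # only covariate 2 is informative and splittable: x1, x3 are constant
  set.seed(41)
  n <- 200
  X <- cbind(x1 = rep(1, n), x2 = rnorm(n), x3 = rep(0, n))
  wt <- rbinom(n, 1, 0.5) - 0.5
  yt <- ifelse(X[, 2] > 0, 1, -1) * wt + 0.05 * rnorm(n)
  cf <- causal_forest(X, yt, wt, forest_params(num_trees = 30,
                                               min_node_size = 20, mtry = 3),
                      seed = 2)
  imp <- variable_importance(cf)
  expect_equal(unname(imp), c(0, 1, 0))

  # stump-free forest: zero vector
  cf0 <- causal_forest(X, yt, wt, forest_params(num_trees = 10,
                                                min_node_size = 150), seed = 2)
  expect_equal(unname(variable_importance(cf0)), c(0, 0, 0))

  # one true modifier among noise gets the top importance
  hits <- 0
  for (s in 1:5) {
    d <- make_cf_data(1500, p = 10,
                      tau_fun = function(X) 2 * (X[, 4] > 0), noise = 0.5,
                      seed = 100 + s)
    lc <- local_center(d$X, d$y, d$w, fast_params(100, 10), seed = s)
    cfm <- causal_forest(d$X, lc$centered$y_tilde, lc$centered$w_tilde,
                         fast_params(150, 10), seed = s)
    if (which.max(variable_importance(cfm)) == 4) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("CATE error shrinks with sample size on a smooth DGP", {
  tau_fun <- function(X) pmin(pmax(X[, 2], -1), 1)
  rmse <- vapply(c(500, 2000, 8000), function(n) {
    d <- make_cf_data(n, p = 4, tau_fun = tau_fun, noise = 0.5, seed = 71)
    lc <- local_center(d$X, d$y, d$w, fast_params(120, 15), seed = 1)
    cf <- causal_forest(d$X, lc$centered$y_tilde, lc$centered$w_tilde,
                        fast_params(120, 15), seed = 2)
    sqrt(mean((predict(cf) - d$tau)^2))
  }, 1.0)
  expect_true(all(diff(rmse) < 0))
})
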