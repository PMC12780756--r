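# AIPW scores and doubly robust average effects.

#' Augmented inverse probability weighted scores
#'
#' Per-person doubly robust effect scores
#' \deqn{\Gamma_i = \hat\tau_i + \frac{W_i - \hat e_i}{\hat e_i(1-\hat e_i)}
#'   \left(Y_i - \hat m_i - (W_i - \hat e_i)\hat\tau_i\right),}
#' on the outcome's scale. All plug-ins must be out-of-bag / cross-fitted and
#' aligned by id; the clipped propensity keeps the scores finite.
#'
#' @param y observed outcome.
#' @param w treatment indicator.
#' @param m_hat out-of-bag outcome predictions E\[Y|X\].
#' @param e_hat out-of-bag clipped propensities E\[W|X\].
#' @param tau_hat out-of-bag CATE estimates.
#' @param ids unique positive integer person ids (default `1:n`).
#' @return data.frame of class `effect_scores`: `person_id`, `gamma`, and the
#'   components.
#' @export
aipw_scores <- function(y, w, m_hat, e_hat, tau_hat, ids = NULL) {
  n <- length(y)
  if (length(w) != n || length(m_hat) != n || length(e_hat) != n ||
      length(tau_hat) != n)
    stop("misaligned inputs: y, w, m_hat, e_hat, tau_hat must have equal length")
  ids <- check_ids(ids, n)
  if (any(e_hat <= 0 | e_hat >= 1)) stop("e_hat must lie strictly inside (0, 1)")
  gamma <- tau_hat + (w - e_hat) / (e_hat * (1 - e_hat)) *
    (y - m_hat - (w - e_hat) * tau_hat)
  structure(data.frame(person_id = ids, gamma = gamma, tau_hat = tau_hat,
                       m_hat = m_hat, e_hat = e_hat, w = w, y = y),
            class = c("effect_scores", "data.frame"))
}

effect_row <- function(target, estimate, se, n) {
  data.frame(target = target, estimate = estimate, se = se,
             ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
             n = n)
}

#' Average treatment effect from AIPW scores
#'
#' ATE is the mean score with se = sd/sqrt(n). ATT weights the scores by the
#' propensity (h_i = e_hat_i), the standard doubly robust
#' effect-on-the-treated weighting, with the standard error from the weighted
#' influence expansion.
#'
#' @param scores an [aipw_scores()] table.
#' @param target `"ATE"` or `"ATT"`.
#' @return one-row data.frame: target, estimate, se, ci_low, ci_high, n.
#' @export
average_effect <- function(scores, target = c("ATE", "ATT")) {
  target <- match.arg(target)
  g <- scores$gamma
  n <- length(g)
  if (n < 2) stop("need at least 2 scores")
  if (target == "ATE") {
    est <- mean(g)
    se <- stats::sd(g) / sqrt(n)
  } else {
    h <- scores$e_hat
    est <- sum(h * g) / sum(h)
    se <- sqrt(sum(h^2 * (g - est)^2)) / sum(h)
  }
  if (se == 0) warning("all scores identical; standard error is zero")
  effect_row(target, est, se, n)
}

#' Per-group average effects
#'
#' Group-wise mean AIPW scores with normal-approximation 95% confidence
#' intervals, ordered by group label. Group sizes weighted by `n` average back
#' to the overall ATE exactly.
#'
#' @param scores an [aipw_scores()] table.
#' @param groups group label per row.
#' @return data.frame with one row per group.
#' @export
group_average_effect <- function(scores, groups) {
  if (length(groups) != nrow(scores)) stop("groups must label every row")
  levs <- sort(unique(groups))
  out <- do.call(rbind, lapply(levs, function(lv) {
    g <- scores$gamma[groups == lv]
    se <- if (length(g) >= 2) stats::sd(g) / sqrt(length(g)) else NA_real_
    cbind(group = lv, effect_row("group-ATE", mean(g), se, length(g)))
  }))
  if (anyNA(out$se))
    warning("groups with fewer than 2 observations: standard error missing")
  out
}
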