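# Exclusion rules and stratified control matching.

#' Apply the cohort exclusion rules
#'
#' Removes every row carrying any exclusion flag and reports counts per reason
#' in the standard order (diagnosis before age 7, missing covariates, death
#' before 18, emigration before 18). A person excluded for several reasons is
#' counted once, under the first matching rule.
#'
#' @param cohort cohort with the four `excl_*` flag columns.
#' @return list with `cohort` (retained rows) and `counts` (reason, n).
#' @export
apply_exclusions <- function(cohort) {
  flags <- exclusion_flag_matrix(cohort)
  first <- max.col(cbind(flags, 0.5) > 0, ties.method = "first")
  excluded <- first <= length(exclusion_reasons())
  counts <- data.frame(
    reason = exclusion_reasons(),
    n = vapply(seq_along(exclusion_reasons()),
               function(k) sum(excluded & first == k), integer(1)))
  list(cohort = cohort[!excluded, , drop = FALSE], counts = counts)
}

stratum_key <- function(cohort) {
  paste(cohort$region, cohort$female, cohort$birth_year, sep = "|")
}

#' Stratified control matching
#'
#' Within each stratum of (region, sex, birth year) containing c treated
#' persons, selects min(`max_per_case` * c, available) controls uniformly
#' without replacement (fewer when the stratum is smaller); all treated persons
#' are retained. Each stratum uses its own RNG stream keyed by
#' (seed, stratum), so the matched sample is invariant to stratum or row
#' reordering. Strata with treated persons but no controls are kept unmatched
#' with a warning.
#'
#' @param cohort post-exclusion cohort with a `treated` column.
#' @param max_per_case maximum controls per treated person (default 26).
#' @param seed integer seed.
#' @return matched sample data.frame (class `matched_sample`) with attributes
#'   `stratum_counts` (per-stratum cases / available / selected) and
#'   `max_per_case`.
#' @export
match_controls <- function(cohort, max_per_case = 26L, seed = 1L) {
  stopifnot(max_per_case >= 1)
  if (!any(cohort$treated == 1)) stop("no treated observations to match")
  if (!any(cohort$treated == 0)) stop("no control observations to match")
  key <- stratum_key(cohort)
  case_strata <- sort(unique(key[cohort$treated == 1]))

  sel_rows <- integer(0)
  counts <- vector("list", length(case_strata))
  for (i in seq_along(case_strata)) {
    s <- case_strata[i]
    in_s <- key == s
    cases <- which(in_s & cohort$treated == 1)
    ctrl <- which(in_s & cohort$treated == 0)
    # id-sorted candidates + per-stratum stream => order-invariant draws
    ctrl <- ctrl[order(cohort$person_id[ctrl])]
    k <- min(max_per_case * length(cases), length(ctrl))
    if (length(ctrl) == 0)
      warning("stratum ", s, " has treated persons but no controls; cases kept unmatched")
    picked <- if (k > 0) {
      set.seed(derive_seed(seed, paste0("stratum:", s)))
      ctrl[sample.int(length(ctrl), k)]
    } else integer(0)
    sel_rows <- c(sel_rows, cases, picked)
    counts[[i]] <- data.frame(stratum = s, cases = length(cases),
                              available = length(ctrl), selected = k)
  }
  out <- cohort[sort(sel_rows), , drop = FALSE]
  attr(out, "stratum_counts") <- do.call(rbind, counts)
  attr(out, "max_per_case") <- as.integer(max_per_case)
  class(out) <- c("matched_sample", class(out))
  out
}
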