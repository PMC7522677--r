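# Synthetic cohorts: independent Bernoulli retrieval outcome per patient
# within each subgroup, at configurable true rates. Used for end-to-end
# testing and for Monte-Carlo calibration of the chi-square comparison.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic patient cohort
#'
#' Draws one independent Bernoulli retrieval outcome per patient within each
#' (cohort, subgroup) stratum at the stratum's true success rate; subgroup
#' sizes are exactly as specified and outcome counts are
#' Binomial(size, rate). Deterministic given `seed`, and the caller's RNG
#' state is left untouched.
#'
#' @param spec Data frame with one row per stratum: columns `cohort`,
#'   `subgroup`, `n` (size, >= 0), `rate` (true success probability in
#'   [0, 1]); an optional `histopathology` column (default `"unknown"`).
#' @param seed Integer RNG seed.
#' @return A patient-records data frame (possibly 0 rows) in the
#'   [compare_cohorts()] format.
#' @examples
#' spec <- data.frame(cohort = c("previous", "new"),
#'                    subgroup = "other", n = c(56, 102),
#'                    rate = c(0.29, 0.45))
#' nrow(synth_cohort(spec, seed = 1))
#' @export
synth_cohort <- function(spec, seed) {
  req <- c("cohort", "subgroup", "n", "rate")
  if (!is.data.frame(spec) || !all(req %in% names(spec)))
    stop("`spec` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(spec$rate < 0 | spec$rate > 1))
    stop("success rates must lie in [0, 1]", call. = FALSE)
  if (any(spec$n < 0 | spec$n != round(spec$n)))
    stop("stratum sizes must be non-negative integers", call. = FALSE)
  if (is.null(spec$histopathology))
    spec$histopathology <- rep("unknown", nrow(spec))
  empty <- data.frame(id = character(), cohort = character(),
                      subgroup = character(), histopathology = character(),
                      outcome = character(), stringsAsFactors = FALSE)
  if (nrow(spec) == 0 || sum(spec$n) == 0) return(empty)
  records <- .with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      n <- spec$n[i]
      if (n == 0) return(NULL)
      data.frame(cohort = spec$cohort[i], subgroup = spec$subgroup[i],
                 histopathology = spec$histopathology[i],
                 outcome = ifelse(stats::runif(n) < spec$rate[i],
                                  "success", "failure"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  records$id <- sprintf("S%04d", seq_len(nrow(records)))
  rownames(records) <- NULL
  .validate_records(
    records[, c("id", "cohort", "subgroup", "histopathology", "outcome")])
}

#' Stratum specification mirroring the published series
#'
#' Convenience builder for [synth_cohort()]: the etiology-subgroup sizes of
#' the two published cohorts with true rates equal to the printed retrieval
#' proportions (strata with n = 0 on one side are kept at size 0 there).
#'
#' @return A `spec` data frame for [synth_cohort()].
#' @export
published_mix_spec <- function() {
  counts <- srr_count_table()
  et <- counts[counts$section == "etiology", ]
  data.frame(cohort = et$cohort, subgroup = et$label, n = et$n,
             rate = ifelse(et$n > 0, et$successes / et$n, 0),
             stringsAsFactors = FALSE)
}

#' Monte-Carlo power / size of the uncorrected chi-square comparison
#'
#' Simulates `reps` independent two-cohort experiments with
#' Binomial(`n1`, `p1`) and Binomial(`n2`, `p2`) success counts and returns
#' the fraction rejected by the uncorrected Pearson chi-square test at level
#' `alpha`. With `p1 = p2` this calibrates the type-I error of the test at
#' the given group sizes; with `p1 != p2` it estimates power. Degenerate
#' replicate tables (an all-success or all-failure outcome margin) cannot be
#' tested and count as non-rejections; their number is attached as attribute
#' `n_degenerate`.
#'
#' The per-replicate statistic is computed vectorized from the closed-form
#' 2x2 Pearson formula; tests cross-check it against [pearson_chi2()].
#'
#' @param n1,n2 Group sizes.
#' @param p1,p2 True success probabilities.
#' @param alpha Significance level (default 0.05).
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer RNG seed.
#' @return Rejection fraction in [0, 1], with attribute `n_degenerate`.
#' @examples
#' power_sim(56, 102, 0.29, 0.45, reps = 1000, seed = 7)
#' @export
power_sim <- function(n1, n2, p1, p2, alpha = 0.05, reps, seed) {
  stopifnot(n1 >= 1, n2 >= 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (reps < 100) stop("`reps` must be at least 100", call. = FALSE)
  .with_seed(seed, {
    s1 <- as.numeric(stats::rbinom(reps, n1, p1))
    s2 <- as.numeric(stats::rbinom(reps, n2, p2))
    f1 <- n1 - s1; f2 <- n2 - s2
    succ <- s1 + s2; fail <- f1 + f2
    degenerate <- succ == 0 | fail == 0
    N <- n1 + n2
    stat <- N * (s1 * f2 - f1 * s2)^2 / (n1 * n2 * succ * fail)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    reject <- !degenerate & p < alpha
    structure(mean(reject), n_degenerate = sum(degenerate))
  })
}
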