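# The published 158-patient microTESE series (56 previous-method patients,
# 2011-2014; 102 new-method patients, 2014-2018), at the level of printed
# counts: successes/n per cohort for the overall series, the six etiology
# subgroups and the three histopathology categories. Only these marginal
# counts are published -- individual patients are not.

#' Published sperm-retrieval count table
#'
#' The success/total counts of the two surgical cohorts (previous vs new
#' microTESE method) as printed: overall, by NOA etiology and by testicular
#' histopathology. These margins are the reproducible content of the
#' clinical series; every statistic this package reproduces is a function of
#' them.
#'
#' @return Data frame with columns `section` (`overall` / `etiology` /
#'   `histopathology`), `label`, `cohort` (`previous` / `new`), `successes`,
#'   `n`.
#' @examples
#' head(srr_count_table())
#' @export
srr_count_table <- function() {
  row <- function(section, label, s_prev, n_prev, s_new, n_new)
    data.frame(section = section, label = label,
               cohort = c("previous", "new"),
               successes = c(s_prev, s_new), n = c(n_prev, n_new),
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    row("overall", "overall", 16, 56, 46, 102),
    row("etiology", "Klinefelter",             1, 8,  5, 11),
    row("etiology", "AZFc deletion",           0, 0,  1, 2),
    row("etiology", "47XYY",                   0, 0,  2, 2),
    row("etiology", "post-chemotherapy",       0, 4,  0, 3),
    row("etiology", "cryptorchidism history",  3, 3,  6, 7),
    row("etiology", "other",                  12, 41, 32, 77),
    row("histopathology", "hypospermatogenesis",      13, 24, 32, 44),
    row("histopathology", "uniform maturation arrest", 0, 2,  8, 9),
    row("histopathology", "Sertoli cell only",         3, 30,  6, 49)
  ))
}

# Northwest-corner allocation: fill a joint table with given row and column
# sums (both non-negative, equal totals). Deterministic; any feasible joint
# structure works because all reproduced statistics are marginal.
.allocate_joint <- function(row_counts, col_counts) {
  stopifnot(sum(row_counts) == sum(col_counts))
  m <- matrix(0L, length(row_counts), length(col_counts))
  i <- 1L; j <- 1L
  r <- row_counts; cl <- col_counts
  while (i <= length(r) && j <= length(cl)) {
    take <- min(r[i], cl[j])
    m[i, j] <- take
    r[i] <- r[i] - take; cl[j] <- cl[j] - take
    if (r[i] == 0L) i <- i + 1L else j <- j + 1L
  }
  m
}

#' Reconstructed 158-patient cohort (synthetic joint structure)
#'
#' Expands [srr_count_table()] into one record per patient. The printed
#' etiology and histopathology margins (sizes and success counts, per
#' cohort) are reproduced *exactly*; the joint assignment of etiology x
#' histopathology within each cohort and outcome is **synthetic** -- it is
#' not published, so a deterministic northwest-corner allocation consistent
#' with every margin is used. Any analysis that only uses margins (i.e.
#' everything in [compare_cohorts()]) is unaffected by that choice.
#'
#' @return A 158-row patient-records data frame (columns `id`, `cohort`,
#'   `subgroup`, `histopathology`, `outcome`).
#' @examples
#' table(reconstruct_cohort()$cohort)
#' @export
reconstruct_cohort <- function() {
  counts <- srr_count_table()
  recs <- list()
  for (cohort in c("previous", "new")) {
    et <- counts[counts$section == "etiology" & counts$cohort == cohort, ]
    hp <- counts[counts$section == "histopathology" & counts$cohort == cohort, ]
    et <- et[match(ETIOLOGIES, et$label), ]
    hp <- hp[match(setdiff(HISTOPATHOLOGIES, "unknown"), hp$label), ]
    for (out in c("success", "failure")) {
      et_n <- if (out == "success") et$successes else et$n - et$successes
      hp_n <- if (out == "success") hp$successes else hp$n - hp$successes
      joint <- .allocate_joint(et_n, hp_n)
      for (i in seq_along(et_n)) for (j in seq_along(hp_n)) {
        k <- joint[i, j]
        if (k > 0)
          recs[[length(recs) + 1L]] <- data.frame(
            cohort = cohort, subgroup = et$label[i],
            histopathology = hp$label[j], outcome = out,
            stringsAsFactors = FALSE)[rep(1, k), ]
      }
    }
  }
  records <- do.call(rbind, recs)
  # stable clinical-looking ids: cohort prefix + running number
  records <- records[order(records$cohort, records$subgroup,
                           records$histopathology, records$outcome), ]
  records$id <- paste0(ifelse(records$cohort == "previous", "P", "N"),
                       stats::ave(seq_len(nrow(records)), records$cohort,
                                  FUN = seq_along))
  rownames(records) <- NULL
  records[, c("id", "cohort", "subgroup", "histopathology", "outcome")]
}
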