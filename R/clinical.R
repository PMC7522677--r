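# Cohort statistics for sperm retrieval rates (SRR): per-subgroup success
# proportions and uncorrected Pearson chi-square comparisons between a
# previous-method and a new-method surgical cohort.

ETIOLOGIES <- c("Klinefelter", "AZFc deletion", "47XYY", "post-chemotherapy",
                "cryptorchidism history", "other")
HISTOPATHOLOGIES <- c("hypospermatogenesis", "uniform maturation arrest",
                      "Sertoli cell only", "unknown")
OUTCOMES <- c("success", "failure")

# Half-up rounding at `decimals` places (R's round() is round-half-even;
# published percentages use half-up). Small eps guards against binary
# representations sitting a hair below .5.
.round_half_up <- function(x, decimals = 0) {
  f <- 10^decimals
  floor(x * f + 0.5 + 1e-9) / f
}

#' Sperm retrieval rate as a printed percentage
#'
#' `100 * successes / n`, rounded half-up to `decimals` places -- the
#' rounding convention used for published retrieval-rate tables (0 decimals
#' for overall rates, 1 decimal for subgroup rates).
#'
#' @param successes,n Non-negative counts, `successes <= n`, `n > 0`.
#' @param decimals Decimal places to keep (default 0).
#' @return Percentage (vectorized over `successes`/`n`).
#' @examples
#' srr(46, 102)      # 45
#' srr(8, 9, 1)      # 88.9
#' @export
srr <- function(successes, n, decimals = 0) {
  if (any(n <= 0)) stop("retrieval rate is undefined for n = 0", call. = FALSE)
  if (any(successes < 0) || any(successes > n))
    stop("need 0 <= successes <= n", call. = FALSE)
  .round_half_up(100 * successes / n, decimals)
}

#' Uncorrected Pearson chi-square test for a 2x2 cohort table
#'
#' Pearson chi-square on the 2x2 success/failure table of two cohorts,
#' *without* Yates continuity correction and with no exact-test fallback,
#' df = 1, upper-tail p. The uncorrected statistic is used deliberately even
#' for small expected counts: it is the variant consistent with the p-values
#' this package reproduces (e.g. 0/2 vs 8/9 gives X^2 = 6.52, p = .011,
#' where a corrected or exact test does not). Interpret small-cell p-values
#' with that caveat.
#'
#' @param successes_g1,failures_g1,successes_g2,failures_g2 Non-negative
#'   counts; each group total and both outcome margins must be positive.
#' @return A list with `statistic`, `df` (always 1) and `p.value`.
#' @examples
#' pearson_chi2(46, 56, 16, 40)  # X^2 = 4.13, p = .042
#' @export
pearson_chi2 <- function(successes_g1, failures_g1, successes_g2, failures_g2) {
  counts <- c(successes_g1, failures_g1, successes_g2, failures_g2)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers", call. = FALSE)
  tab <- matrix(round(counts), nrow = 2, byrow = TRUE,
                dimnames = list(group = c("g1", "g2"),
                                outcome = c("success", "failure")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a row or column margin is zero, ",
         "the chi-square test is undefined", call. = FALSE)
  # small expected counts warn about the chi-square approximation; the
  # uncorrected variant is used deliberately (see Details), so keep quiet
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L,
       p.value = unname(ct$p.value))
}

.validate_records <- function(records) {
  req <- c("id", "cohort", "subgroup", "histopathology", "outcome")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("patient records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(records$subgroup %in% ETIOLOGIES))
  if (length(bad))
    stop("unknown etiology subgroup ", dQuote(records$subgroup[bad[1]]),
         " at row ", bad[1], "; expected one of: ",
         paste(ETIOLOGIES, collapse = ", "), call. = FALSE)
  bad <- which(!(records$histopathology %in% HISTOPATHOLOGIES))
  if (length(bad))
    stop("unknown histopathology ", dQuote(records$histopathology[bad[1]]),
         " at row ", bad[1], "; expected one of: ",
         paste(HISTOPATHOLOGIES, collapse = ", "), call. = FALSE)
  bad <- which(!(records$outcome %in% OUTCOMES))
  if (length(bad))
    stop("malformed outcome ", dQuote(as.character(records$outcome[bad[1]])),
         " at row ", bad[1], "; expected success/failure", call. = FALSE)
  invisible(records)
}

.cohort_levels <- function(cohorts) {
  lv <- unique(cohorts)
  if (length(lv) != 2L)
    stop("need exactly two cohorts; found: ", paste(lv, collapse = ", "),
         call. = FALSE)
  # conventional order: previous method first, then new
  if (setequal(lv, c("previous", "new"))) c("previous", "new") else sort(lv)
}

# One comparison row: SRRs per cohort plus the chi-square call. p is NA
# ("not computable") when a cohort side is empty or an outcome margin is
# zero -- the dash rows of a published table.
.summary_row <- function(label, s1, n1, s2, n2, alpha, decimals) {
  computable <- n1 > 0 && n2 > 0 && (s1 + s2) > 0 && (s1 + s2) < (n1 + n2)
  if (computable) {
    ct <- pearson_chi2(s1, n1 - s1, s2, n2 - s2)
    stat <- ct$statistic; p <- ct$p.value
  } else {
    stat <- NA_real_; p <- NA_real_
  }
  data.frame(
    label = label,
    successes_g1 = s1, n_g1 = n1,
    srr_g1 = if (n1 > 0) srr(s1, n1, decimals) else NA_real_,
    successes_g2 = s2, n_g2 = n2,
    srr_g2 = if (n2 > 0) srr(s2, n2, decimals) else NA_real_,
    statistic = stat, p.value = p,
    significant = if (is.na(p)) NA else p < alpha,
    stringsAsFactors = FALSE)
}

#' Compare sperm retrieval between two cohorts, overall and by subgroup
#'
#' Builds the retrieval-rate comparison table from patient records: an
#' overall row, one row per etiology subgroup and one per histopathology
#' category, each with per-cohort successes/n, the SRR percentage (half-up,
#' 0 decimals overall / 1 decimal for subgroups), the uncorrected Pearson
#' chi-square p-value and a significance flag at `alpha`. Rows where one
#' cohort is empty, or where every patient has the same outcome, get `NA`
#' p-values (not computable). No multiple-testing adjustment is applied;
#' each row is tested at `alpha` on its own.
#'
#' @param records Data frame of patient records with columns `id`, `cohort`
#'   (exactly two labels; `"previous"`/`"new"` are ordered conventionally),
#'   `subgroup` (etiology), `histopathology`, `outcome`
#'   (`"success"`/`"failure"`). See [read_cohort_csv()].
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"cohort_comparison"`: a data frame of
#'   comparison rows with a `section` column (`overall`, `etiology`,
#'   `histopathology`) and attributes `cohorts` and `alpha`.
#' @examples
#' comp <- compare_cohorts(reconstruct_cohort())
#' subset(comp, section == "overall")
#' @export
compare_cohorts <- function(records, alpha = 0.05) {
  records <- .validate_records(records)
  cohorts <- .cohort_levels(records$cohort)
  g1 <- records[records$cohort == cohorts[1], ]
  g2 <- records[records$cohort == cohorts[2], ]
  n_success <- function(df) sum(df$outcome == "success")

  rows <- list()
  add <- function(section, row) {
    row$section <- section
    rows[[length(rows) + 1L]] <<- row
  }
  add("overall", .summary_row("overall", n_success(g1), nrow(g1),
                              n_success(g2), nrow(g2), alpha, decimals = 0))
  for (et in ETIOLOGIES) {
    s1 <- g1[g1$subgroup == et, ]; s2 <- g2[g2$subgroup == et, ]
    if (nrow(s1) + nrow(s2) == 0) next
    add("etiology", .summary_row(et, n_success(s1), nrow(s1),
                                 n_success(s2), nrow(s2), alpha, decimals = 1))
  }
  for (hp in setdiff(HISTOPATHOLOGIES, "unknown")) {
    s1 <- g1[g1$histopathology == hp, ]; s2 <- g2[g2$histopathology == hp, ]
    if (nrow(s1) + nrow(s2) == 0) next
    add("histopathology", .summary_row(hp, n_success(s1), nrow(s1),
                                       n_success(s2), nrow(s2), alpha,
                                       decimals = 1))
  }
  out <- do.call(rbind, rows)
  out <- out[, c("section", setdiff(names(out), "section"))]
  rownames(out) <- NULL
  structure(out, class = c("cohort_comparison", "data.frame"),
            cohorts = cohorts, alpha = alpha)
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cohorts <- attr(x, "cohorts"); alpha <- attr(x, "alpha")
  cat(sprintf("Sperm retrieval rates: %s vs %s method (alpha = %g)\n\n",
              cohorts[1], cohorts[2], alpha))
  fmt_cell <- function(s, n, pct) {
    ifelse(n == 0, "0/0", sprintf("%d/%d (%g%%)", s, n, pct))
  }
  pcol <- ifelse(is.na(x$p.value), "-",
                 ifelse(x$significant, sprintf("%.3f *", x$p.value), "NS"))
  df <- data.frame(
    subgroup = x$label,
    check.names = FALSE, stringsAsFactors = FALSE)
  df[[cohorts[1]]] <- fmt_cell(x$successes_g1, x$n_g1, x$srr_g1)
  df[[cohorts[2]]] <- fmt_cell(x$successes_g2, x$n_g2, x$srr_g2)
  df[["P"]] <- pcol
  for (sec in unique(x$section)) {
    cat("--", sec, "--\n")
    print(df[x$section == sec, ], row.names = FALSE, right = FALSE)
  }
  invisible(x)
}

#' Read / write patient-record CSV files
#'
#' The on-disk cohort format: UTF-8 CSV with header columns `id`, `cohort`,
#' `subgroup`, `histopathology`, `outcome`; subgroup/histopathology/outcome
#' vocabularies as in [compare_cohorts()]. Validation errors cite the first
#' offending data row.
#'
#' @param path File path.
#' @return `read_cohort_csv()`: a validated records data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  .validate_records(records)
}

#' @rdname read_cohort_csv
#' @param records A patient-records data frame.
#' @return `write_cohort_csv()`: `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  .validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
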