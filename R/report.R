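# Report generation and self-verification: the back-end of the command-line
# interface (inst/cli/microtese.R). Reports are JSON (machine-diffable);
# human-readable tables go to the console.

.pkg_version <- function() as.character(utils::packageVersion("microtese"))

.validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list / JSON object", call. = FALSE)
  has_axes <- !is.null(config$axes_mm); has_ratios <- !is.null(config$ratios)
  if (has_axes == has_ratios)
    stop("config error at `axes_mm`/`ratios`: provide exactly one of the two",
         call. = FALSE)
  if (is.null(config$l))
    stop("config error at `l`: slice width (mm) is required", call. = FALSE)
  if (!is.numeric(config$l) || length(config$l) != 1L || config$l <= 0)
    stop("config error at `l`: must be a single positive number", call. = FALSE)
  if (has_ratios && (!is.numeric(config$ratios) || length(config$ratios) != 3L))
    stop("config error at `ratios`: need three numbers (a, b, c)", call. = FALSE)
  if (has_axes && (!is.numeric(config$axes_mm) || length(config$axes_mm) != 3L))
    stop("config error at `axes_mm`: need three semi-axis lengths in mm",
         call. = FALSE)
  config
}

#' Simulate all feasible strategies and write a JSON report
#'
#' Wraps [rank_strategies()] / [recommend()] for scripted use: validates a
#' run configuration, computes the per-strategy area breakdown and ranking,
#' and (optionally) serializes a self-describing JSON report with a
#' provenance block (package version, inputs, seed).
#'
#' @param config A list (e.g. parsed from a JSON config file) with exactly
#'   one of `ratios` (three numbers `a, b, c`) or `axes_mm` (three measured
#'   semi-axis lengths in mm), plus `l` (slice width, mm) and optionally
#'   `seed` (recorded in provenance; the simulation itself is
#'   deterministic).
#' @param out Optional path for the JSON report.
#' @return The report, invisibly: a list with `provenance`, `testis`,
#'   `strategies` (per-strategy breakdowns), `ranking` and `differences`.
#' @examples
#' rep <- simulate_report(list(ratios = c(3, 2, 1), l = 1))
#' rep$ranking
#' @export
simulate_report <- function(config, out = NULL) {
  config <- .validate_config(config)
  if (!is.null(config$ratios)) {
    r <- sort(config$ratios, decreasing = TRUE)
    testis <- testis_ellipsoid(r[1], r[2], r[3], l = config$l)
    ranking <- rank_strategies(testis)
  } else {
    ranking <- recommend(config$axes_mm, config$l)
    testis <- ranking$testis
  }
  report <- list(
    provenance = list(
      package = "microtese", version = .pkg_version(),
      inputs = config[!vapply(config, is.null, TRUE)],
      seed = if (is.null(config$seed)) NA_integer_ else config$seed,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    testis = ranking$testis[c("a", "b", "c", "l", "A", "B", "C")],
    strategies = lapply(ranking$breakdowns, function(b)
      b[c("method_label", "tunical", "slicing", "bivalve_face_area",
          "slice_face_sum", "total")]),
    ranking = ranking$ranking,
    ties = ranking$ties,
    differences = ranking$differences)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}

#' Run the package's geometric invariant suite
#'
#' Self-verification harness: checks, over an exhaustive grid of integer
#' testes with longest ratio up to `depth`, that (i) the closed-form slice
#' sums equal direct summation (relative 1e-9, all three orientations),
#' (ii) quadrature agrees with the closed-form cross-sections (relative
#' 1e-4), (iii) the strategy ranking is 1 > 2 > 3 > 4 for every strictly
#' ordered triple with the three adjacent differences matching their closed
#' forms, and (iv) the slice-sum-times-width continuum limit converges
#' monotonically to twice the ellipsoid volume.
#'
#' @param depth Largest ratio `a` in the grids (>= 2; default 10).
#' @param resolution Quadrature resolution (default 1024).
#' @param tamper Test hook: a perturbation (mm^2) added to every closed-form
#'   slice sum before comparison, to verify that the harness actually
#'   detects broken identities. Leave at 0.
#' @return A list with `pass` (logical) and `failures` (data frame of
#'   check/detail rows, empty when all pass).
#' @examples
#' verify_invariants(depth = 3)$pass
#' @export
verify_invariants <- function(depth = 10, resolution = 1024, tamper = 0) {
  if (!is.numeric(depth) || depth < 2) stop("`depth` must be >= 2", call. = FALSE)
  failures <- list()
  fail <- function(check, detail)
    failures[[length(failures) + 1L]] <<- data.frame(
      check = check, detail = detail, stringsAsFactors = FALSE)

  triples <- expand.grid(c = 1:depth, b = 1:depth, a = 1:depth)
  triples <- triples[triples$a >= triples$b & triples$b >= triples$c, ]

  # (i) closed form vs direct summation
  for (k in seq_len(nrow(triples))) {
    t <- testis_ellipsoid(triples$a[k], triples$b[k], triples$c[k], l = 1)
    for (o in ORIENTATIONS) {
      cl <- slice_face_sum_closed(t, o) + tamper
      di <- slice_face_sum_direct(t, o)
      if (abs(cl - di) > 1e-9 * max(di, 1))
        fail("closed_vs_direct",
             sprintf("(%d,%d,%d) %s: closed %.12g direct %.12g",
                     t$a, t$b, t$c, o, cl, di))
    }
  }

  # (ii) quadrature oracle on a deterministic sample of sections
  some <- triples[seq(1, nrow(triples), length.out = min(8, nrow(triples))), ]
  for (k in seq_len(nrow(some))) {
    t <- testis_ellipsoid(some$a[k], some$b[k], some$c[k], l = 1)
    for (o in ORIENTATIONS) {
      r <- .axis_map(t, o)$r
      for (idx in unique(c(0, r %/% 2, r - 1))) {
        q <- plane_section_area_quadrature(t, o, idx, resolution)
        h <- 2 * half_cross_section_area(t, o, idx)
        if (h > 0 && abs(q - h) > 1e-4 * h)
          fail("quadrature", sprintf("(%d,%d,%d) %s idx %d: quad %.8g closed %.8g",
                                     t$a, t$b, t$c, o, idx, q, h))
      }
    }
  }

  # (iii) strict ranking + printed adjacent differences
  strict <- triples[triples$a > triples$b & triples$b > triples$c, ]
  for (k in seq_len(nrow(strict))) {
    t <- testis_ellipsoid(strict$a[k], strict$b[k], strict$c[k], l = 1)
    totals <- vapply(1:4, function(m) total_search_area(t, m)$total, 0) + tamper
    if (!all(diff(totals) < 0))
      fail("ranking", sprintf("(%d,%d,%d): totals not decreasing", t$a, t$b, t$c))
    for (pair in list(c(1, 2), c(2, 3), c(3, 4))) {
      d <- totals[pair[1]] - totals[pair[2]]
      dc <- difference_closed_form(t, pair[1], pair[2])
      if (abs(d - dc) > 1e-9 * max(abs(dc), 1))
        fail("difference_closed_form",
             sprintf("(%d,%d,%d) pair %d-%d: %.12g vs %.12g",
                     t$a, t$b, t$c, pair[1], pair[2], d, dc))
    }
  }

  # (iv) continuum limit: fixed physical organ (semi-axes 20 x 10 x 4 mm,
  # ratio 10:5:2 so every refinement keeps integer ratios), shrinking width
  A <- 20
  errs <- vapply(c(10, 20, 40, 80), function(a) {
    l <- A / a
    t <- testis_ellipsoid(a, a / 2, a / 5, l = l)
    lim <- 2 * ellipsoid_volume(t)
    abs((slice_face_sum_direct(t, "transverse") + tamper) * l - lim) / lim
  }, 0)
  if (!all(diff(errs) < 0))
    fail("continuum_limit", paste("errors not monotone:",
                                  paste(signif(errs, 4), collapse = " ")))

  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(check = character(), detail = character())
  list(pass = nrow(failures) == 0L, failures = failures)
}

#' Cohort statistics from a patient-record CSV
#'
#' Reads a patient CSV (see [read_cohort_csv()]), runs [compare_cohorts()],
#' prints the aligned comparison table, and optionally writes the rows as
#' JSON.
#'
#' @param csv_path Path to the patient-record CSV.
#' @param alpha Significance level (default 0.05).
#' @param json_out Optional path for a JSON copy of the summary rows.
#' @return The [compare_cohorts()] object, invisibly.
#' @export
cohort_stats <- function(csv_path, alpha = 0.05, json_out = NULL) {
  comp <- compare_cohorts(read_cohort_csv(csv_path), alpha = alpha)
  print(comp)
  if (!is.null(json_out))
    jsonlite::write_json(
      list(alpha = alpha, cohorts = attr(comp, "cohorts"),
           rows = as.data.frame(comp)),
      json_out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(comp)
}

#' Generate a synthetic cohort CSV
#'
#' Wraps [synth_cohort()]: reads a stratum specification (CSV with columns
#' `cohort`, `subgroup`, `n`, `rate`, or an already-loaded data frame),
#' simulates the cohort under `seed`, and writes the patient CSV. An empty
#' specification yields a header-only CSV. Byte-identical output for
#' identical inputs and seed.
#'
#' @param spec A spec data frame or path to a spec CSV.
#' @param seed Integer RNG seed.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_synth_cohort <- function(spec, seed, out) {
  if (is.character(spec)) spec <- utils::read.csv(spec, stringsAsFactors = FALSE)
  records <- synth_cohort(spec, seed)
  utils::write.csv(records, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}
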