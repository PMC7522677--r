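# Incision strategies: tunical incision orientation x parenchymal slicing
# plane. The tunical incision bivalves the testis, exposing a central cut
# plane; slices must stay attached to the tunica, so slicing parallel to the
# bivalve exposure plane is infeasible (the pieces would detach and fall
# apart). That leaves 4 of the 6 combinations, labelled 1-4:
#   1 longitudinal + transverse slices
#   2 longitudinal + sagittal slices
#   3 transverse   + sagittal slices
#   4 transverse   + coronal slices
TUNICAL_INCISIONS <- c("longitudinal", "transverse")

# Orientation of the bivalve exposure plane (named by its normal axis, like
# slicing planes): a longitudinal tunical incision exposes the central X-Y
# plane (normal Z, i.e. "coronal"); a transverse one the Y-Z plane
# (normal X, "transverse").
.exposure_orientation <- function(tunical) {
  tunical <- match.arg(tunical, TUNICAL_INCISIONS)
  switch(tunical, longitudinal = "coronal", transverse = "transverse")
}

#' Enumerate all incision strategies
#'
#' All six combinations of tunical incision (longitudinal / transverse) and
#' parenchymal slicing plane (transverse / sagittal / coronal), with the
#' feasibility rule applied as a geometric predicate: a strategy is feasible
#' if and only if its slicing plane is *not* parallel to the bivalve
#' exposure plane (otherwise the slices detach from the tunica albuginea).
#' Exactly four combinations survive; they carry method labels 1-4.
#'
#' @return A data frame with columns `tunical`, `slicing`, `feasible`
#'   (logical) and `method_label` (1-4, `NA` for the two infeasible
#'   combinations).
#' @examples
#' enumerate_strategies()
#' @export
enumerate_strategies <- function() {
  grid <- expand.grid(slicing = ORIENTATIONS, tunical = TUNICAL_INCISIONS,
                      stringsAsFactors = FALSE)[, c("tunical", "slicing")]
  grid$feasible <- mapply(function(tun, sl)
    !identical(.exposure_orientation(tun), sl), grid$tunical, grid$slicing)
  labels <- data.frame(
    tunical = c("longitudinal", "longitudinal", "transverse", "transverse"),
    slicing = c("transverse", "sagittal", "sagittal", "coronal"),
    method_label = 1:4, stringsAsFactors = FALSE)
  grid$method_label <- labels$method_label[
    match(paste(grid$tunical, grid$slicing),
          paste(labels$tunical, labels$slicing))]
  stopifnot(sum(grid$feasible) == 4L,
            identical(is.na(grid$method_label), !grid$feasible))
  rownames(grid) <- NULL
  grid
}

.strategy_by_label <- function(label) {
  s <- enumerate_strategies()
  row <- s[!is.na(s$method_label) & s$method_label == label, ]
  if (nrow(row) != 1L)
    stop("`method` must be one of the feasible strategy labels 1, 2, 3, 4",
         call. = FALSE)
  row
}

#' Cut-plane area of the bivalved testis
#'
#' The tunical incision opens the testis like a book, exposing the two faces
#' of a central cross-section: area `2*pi*a*b*l^2` for a longitudinal
#' incision (central X-Y ellipse) and `2*pi*b*c*l^2` for a transverse one
#' (central Y-Z ellipse).
#'
#' @param testis A [testis_ellipsoid()].
#' @param tunical `"longitudinal"` or `"transverse"`.
#' @return Exposed bivalve face area in mm^2 (both faces).
#' @examples
#' bivalve_face_area(testis_ellipsoid(3, 2, 1), "longitudinal")  # 12*pi
#' @export
bivalve_face_area <- function(testis, tunical) {
  stopifnot(inherits(testis, "testis_ellipsoid"))
  tunical <- match.arg(tunical, TUNICAL_INCISIONS)
  # two faces of the central section normal to the exposure orientation
  2 * half_cross_section_area(testis, .exposure_orientation(tunical), 0) * 2
}

#' Total searchable area of one strategy
#'
#' Total cut-surface area a surgeon can search under a given strategy: the
#' two bivalve faces plus the slice-face sum for the strategy's slicing
#' plane (closed form in strict mode, direct summation for generalized
#' ratios).
#'
#' @param testis A [testis_ellipsoid()].
#' @param method Feasible method label 1-4, or a one-row strategy (a row of
#'   [enumerate_strategies()] / a list with `tunical` and `slicing`).
#' @return An object of class `"area_breakdown"`: list with
#'   `bivalve_face_area`, `slice_face_sum`, `total` (mm^2), `method_label`,
#'   `tunical`, `slicing`, and `closed_form` (whether the closed-form sum
#'   was used).
#' @examples
#' total_search_area(testis_ellipsoid(3, 2, 1), 1)  # 248*pi/9
#' @export
total_search_area <- function(testis, method) {
  stopifnot(inherits(testis, "testis_ellipsoid"))
  if (is.numeric(method) && length(method) == 1L) {
    strat <- .strategy_by_label(method)
  } else if (is.list(method) && !is.null(method$tunical) && !is.null(method$slicing)) {
    strat <- method
  } else stop("`method` must be a label 1-4 or a strategy row", call. = FALSE)
  tunical <- match.arg(strat$tunical, TUNICAL_INCISIONS)
  slicing <- match.arg(strat$slicing, ORIENTATIONS)
  if (identical(.exposure_orientation(tunical), slicing))
    stop("infeasible strategy (", tunical, " tunical incision + ", slicing,
         " slices): the sliced pieces would be detached from the tunica ",
         "albuginea and fall apart", call. = FALSE)
  biv <- bivalve_face_area(testis, tunical)
  slc <- if (testis$strict) slice_face_sum_closed(testis, slicing)
         else slice_face_sum_direct(testis, slicing)
  lbl <- enumerate_strategies()
  lbl <- lbl$method_label[lbl$tunical == tunical & lbl$slicing == slicing]
  structure(
    list(bivalve_face_area = biv, slice_face_sum = slc, total = biv + slc,
         method_label = lbl, tunical = tunical, slicing = slicing,
         closed_form = testis$strict),
    class = "area_breakdown")
}

#' @export
print.area_breakdown <- function(x, ...) {
  cat(sprintf("Method %d: %s tunical incision + %s slices\n",
              x$method_label, x$tunical, x$slicing))
  cat(sprintf("  bivalve faces %9.3f mm^2\n", x$bivalve_face_area))
  cat(sprintf("  slice faces   %9.3f mm^2%s\n", x$slice_face_sum,
              if (x$closed_form) "" else "  (direct summation)"))
  cat(sprintf("  total         %9.3f mm^2\n", x$total))
  invisible(x)
}

#' Signed difference in total searchable area between two strategies
#'
#' `total(method i) - total(method j)`. For the adjacent method pairs the
#' difference also has a printed closed form (see
#' [difference_closed_form()]); for any strictly ordered ellipsoid
#' (`a > b > c`) all three adjacent differences are strictly positive, which
#' is what makes method 1 the maximizer.
#'
#' @param testis A [testis_ellipsoid()].
#' @param i,j Feasible method labels (1-4).
#' @return Signed area difference in mm^2.
#' @examples
#' pairwise_difference(testis_ellipsoid(3, 2, 1), 2, 3)  # 8*pi
#' @export
pairwise_difference <- function(testis, i, j) {
  total_search_area(testis, i)$total - total_search_area(testis, j)$total
}

#' Closed-form adjacent strategy differences
#'
#' The three adjacent differences in total searchable area reduce to:
#' \deqn{T_1 - T_2 = 2 c l^2 \frac{a^2 - b^2}{3ab}\pi, \quad
#'       T_2 - T_3 = 2 b l^2 (a - c)\pi, \quad
#'       T_3 - T_4 = 2 a l^2 \frac{b^2 - c^2}{3bc}\pi,}
#' each strictly positive when `a > b > c`. Used as the independent check on
#' [pairwise_difference()].
#'
#' @param testis A [testis_ellipsoid()] (strict mode).
#' @param i,j Adjacent method labels: (1,2), (2,3) or (3,4).
#' @return Area difference in mm^2.
#' @export
difference_closed_form <- function(testis, i, j) {
  stopifnot(inherits(testis, "testis_ellipsoid"), testis$strict)
  key <- paste(i, j)
  with(testis, switch(key,
    "1 2" = 2 * c * l^2 * (a^2 - b^2) / (3 * a * b) * pi,
    "2 3" = 2 * b * l^2 * (a - c) * pi,
    "3 4" = 2 * a * l^2 * (b^2 - c^2) / (3 * b * c) * pi,
    stop("closed forms exist only for adjacent pairs (1,2), (2,3), (3,4)",
         call. = FALSE)))
}

#' Rank the feasible microTESE strategies by searchable area
#'
#' The central computation of the package: evaluates the total searchable
#' cut-surface area of all four feasible strategies for a given ellipsoid
#' testis and ranks them. For any strictly ordered testis (`a > b > c`) the
#' ranking is method 1 > 2 > 3 > 4 -- a longitudinal tunical incision with
#' transverse parenchymal slices maximizes the searchable area. Ties (when
#' `a = b` or `b = c`) are broken by method label and reported.
#'
#' @param testis A [testis_ellipsoid()].
#' @return An object of class `"strategy_ranking"`: list with `testis`, a
#'   per-strategy `table` (data frame: method, tunical, slicing, areas),
#'   `ranking` (method labels, best first), `ties` (list of tied label
#'   groups, empty if none) and the 4x4 antisymmetric `differences` matrix.
#' @examples
#' r <- rank_strategies(testis_ellipsoid(3, 2, 1))
#' r$ranking
#' summary(r)
#' @export
rank_strategies <- function(testis) {
  stopifnot(inherits(testis, "testis_ellipsoid"))
  breakdowns <- lapply(1:4, function(m) total_search_area(testis, m))
  tab <- data.frame(
    method = 1:4,
    tunical = vapply(breakdowns, `[[`, "", "tunical"),
    slicing = vapply(breakdowns, `[[`, "", "slicing"),
    bivalve_face_area = vapply(breakdowns, `[[`, 0, "bivalve_face_area"),
    slice_face_sum = vapply(breakdowns, `[[`, 0, "slice_face_sum"),
    total = vapply(breakdowns, `[[`, 0, "total"),
    stringsAsFactors = FALSE)
  # decreasing total, ties broken by ascending label
  ord <- order(-tab$total, tab$method)
  totals <- tab$total
  tol <- 1e-9 * max(totals)
  grp <- cumsum(c(TRUE, -diff(totals[ord]) > tol))
  tie_groups <- split(tab$method[ord], grp)
  ties <- Filter(function(g) length(g) > 1L, unname(tie_groups))
  diffs <- outer(totals, totals, `-`)
  dimnames(diffs) <- list(paste0("m", 1:4), paste0("m", 1:4))
  structure(
    list(testis = testis, table = tab, ranking = tab$method[ord],
         ties = ties, differences = diffs, breakdowns = breakdowns),
    class = "strategy_ranking")
}

#' @export
print.strategy_ranking <- function(x, digits = 3, ...) {
  t <- x$testis
  cat(sprintf("microTESE strategy ranking for a %g:%g:%g ellipsoid testis (l = %g mm)\n",
              t$a, t$b, t$c, t$l))
  tab <- x$table[match(x$ranking, x$table$method), ]
  tab$rank <- seq_len(nrow(tab))
  out <- data.frame(
    rank = tab$rank, method = tab$method,
    strategy = sprintf("%s + %s slices", tab$tunical, tab$slicing),
    `total mm^2` = round(tab$total, digits), check.names = FALSE)
  print(out, row.names = FALSE)
  if (length(x$ties))
    cat("Ties (equal total area): ",
        paste(vapply(x$ties, function(g) paste(g, collapse = " = "), ""),
              collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.strategy_ranking <- function(object, ...) {
  x <- object
  print(x)
  cat("\nArea breakdown (mm^2):\n")
  tab <- x$table
  tab[, 4:6] <- round(tab[, 4:6], 3)
  print(tab, row.names = FALSE)
  best <- x$ranking[1]; second <- x$ranking[2]
  gain <- x$differences[best, second]
  cat(sprintf("\nBest strategy: method %d (%s tunical incision, %s slices)\n",
              best, tab$tunical[tab$method == best], tab$slicing[tab$method == best]))
  cat(sprintf("Margin over runner-up: %.3f mm^2 (%.2f%%)\n",
              gain, 100 * gain / x$table$total[x$table$method == second]))
  invisible(x)
}

#' @export
plot.strategy_ranking <- function(x, ...) {
  tab <- x$table
  m <- rbind(tab$bivalve_face_area, tab$slice_face_sum)
  graphics::barplot(
    m, names.arg = paste0("method ", tab$method),
    legend.text = c("bivalve faces", "slice faces"),
    args.legend = list(x = "topright", bty = "n"),
    ylab = expression("searchable area (mm"^2 * ")"),
    main = sprintf("Searchable area by strategy (a:b:c = %g:%g:%g, l = %g mm)",
                   x$testis$a, x$testis$b, x$testis$c, x$testis$l),
    ...)
  invisible(x)
}

#' Recommend an incision strategy from measured testis dimensions
#'
#' Clinical front-end: takes the three measured semi-axis lengths in mm (any
#' order) and the intended slice width, derives the integer ratio model by
#' rounding each semi-axis over `l` (reporting the rounding residual), and
#' ranks the strategies.
#'
#' @param axes_mm Numeric vector of the three semi-axis lengths in mm.
#' @param l_mm Slice width in mm (clinically 2-3 mm); must be smaller than
#'   every semi-axis.
#' @return An object of class `"microtese_recommendation"`: the
#'   `strategy_ranking` plus `axes_mm` (sorted), `ratios`, `residuals`
#'   (axes_mm / l_mm minus the rounded ratios) and `pct_gain` of the best
#'   strategy over the runner-up.
#' @examples
#' recommend(c(40, 25, 20), l_mm = 2.5)
#' @export
recommend <- function(axes_mm, l_mm) {
  if (!is.numeric(axes_mm) || length(axes_mm) != 3L || any(!is.finite(axes_mm)) ||
      any(axes_mm <= 0))
    stop("`axes_mm` must be three positive semi-axis lengths in mm", call. = FALSE)
  if (!is.numeric(l_mm) || length(l_mm) != 1L || !is.finite(l_mm) || l_mm <= 0)
    stop("`l_mm` must be a single positive slice width in mm", call. = FALSE)
  axes_mm <- sort(axes_mm, decreasing = TRUE)
  if (min(axes_mm) <= l_mm)
    stop("slice width l_mm = ", l_mm, " mm must be smaller than the shortest ",
         "semi-axis (", min(axes_mm), " mm)", call. = FALSE)
  raw <- axes_mm / l_mm
  ratios <- pmax(1, round(raw))
  testis <- testis_ellipsoid(ratios[1], ratios[2], ratios[3], l = l_mm)
  ranking <- rank_strategies(testis)
  best <- ranking$ranking[1]; second <- ranking$ranking[2]
  gain <- ranking$differences[best, second]
  structure(
    c(ranking,
      list(axes_mm = axes_mm, ratios = ratios, residuals = raw - ratios,
           pct_gain = 100 * gain /
             ranking$table$total[ranking$table$method == second])),
    class = c("microtese_recommendation", "strategy_ranking"))
}

#' @export
print.microtese_recommendation <- function(x, ...) {
  cat(sprintf("Testis semi-axes %s mm, slice width %g mm -> ratio model %s\n",
              paste(x$axes_mm, collapse = " x "), x$testis$l,
              paste(x$ratios, collapse = ":")))
  if (any(abs(x$residuals) > 1e-9))
    cat(sprintf("  (ratios rounded; residuals %s slice widths)\n",
                paste(sprintf("%+.2f", x$residuals), collapse = ", ")))
  NextMethod()
  cat(sprintf("Recommended: method %d; %.2f%% more searchable area than the runner-up\n",
              x$ranking[1], x$pct_gain))
  invisible(x)
}
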