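#' Ellipsoid testis model
#'
#' Constructs the dimensionless ellipsoid model of the testis on which all
#' surface-area computations operate. The testis is described by semi-axis
#' ratios `a >= b >= c` (longest to shortest) and a physical slice width `l`
#' in mm; the physical semi-axes are `A = a*l`, `B = b*l`, `C = c*l`, so the
#' surface satisfies
#' \deqn{\frac{x^2}{(al)^2} + \frac{y^2}{(bl)^2} + \frac{z^2}{(cl)^2} = 1.}
#' The long axis lies along X; sagittal planes (normal Y) are X-Z planes and
#' coronal planes (normal Z) are X-Y planes. Note that `a*l`, `b*l`, `c*l`
#' are *semi*-axes: the full axial lengths of the organ are `2*a*l` etc.
#'
#' In strict mode (the default) `a`, `b`, `c` must be integers, which is what
#' makes the closed-form slice sums over integer cut positions available and
#' the strict strategy ranking provable. Generalized mode accepts any
#' positive reals; slice sums are then computed by direct summation over the
#' integer cut lattice and the closed forms are refused.
#'
#' @param a,b,c Positive semi-axis ratios, `a >= b >= c`. Integers (within
#'   numeric fuzz) when `strict = TRUE`, in which case also `c >= 1`.
#' @param l Slice width in mm (> 0). Clinically 2-3 mm; defaults to 1 so that
#'   areas come out in units of `l^2`.
#' @param strict Require integer ratios (default `TRUE`).
#' @return An object of class `"testis_ellipsoid"`: a list with elements
#'   `a`, `b`, `c`, `l`, `strict` and the physical semi-axes `A`, `B`, `C`.
#' @examples
#' testis_ellipsoid(3, 2, 1)
#' testis_ellipsoid(16, 10, 8, l = 2.5)
#' @seealso [rank_strategies()], [slice_face_sum_closed()]
#' @export
testis_ellipsoid <- function(a, b, c, l = 1, strict = TRUE) {
  for (nm in c("a", "b", "c", "l")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
  }
  if (!(a >= b && b >= c))
    stop("semi-axis ratios must be ordered a >= b >= c (longest to shortest); got (",
         a, ", ", b, ", ", c, ")", call. = FALSE)
  if (strict) {
    if (any(abs(c(a, b, c) - round(c(a, b, c))) > 1e-8))
      stop("strict mode requires integer ratios (a, b, c); use ",
           "`strict = FALSE` for the generalized direct-summation mode",
           call. = FALSE)
    a <- round(a); b <- round(b); c <- round(c)
    if (c < 1)
      stop("strict mode requires c >= 1", call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, l = l, strict = strict,
         A = a * l, B = b * l, C = c * l),
    class = "testis_ellipsoid"
  )
}

#' @export
print.testis_ellipsoid <- function(x, ...) {
  cat("Ellipsoid testis model", if (!x$strict) "(generalized ratios)", "\n")
  cat(sprintf("  ratios   a:b:c = %g:%g:%g   slice width l = %g mm\n",
              x$a, x$b, x$c, x$l))
  cat(sprintf("  semi-axes A, B, C = %g, %g, %g mm  (volume %.2f mm^3)\n",
              x$A, x$B, x$C, ellipsoid_volume(x)))
  invisible(x)
}

#' Ellipsoid volume
#'
#' Volume of the testis model, `(4/3) * pi * A * B * C` with physical
#' semi-axes `A = a*l` etc. Used by the continuum-limit check: as the slice
#' width shrinks, slice-face area times width converges to twice the volume
#' (each cut exposes two faces).
#'
#' @param testis A [testis_ellipsoid()].
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(testis_ellipsoid(1, 1, 1))  # unit sphere, 4*pi/3
#' @export
ellipsoid_volume <- function(testis) {
  stopifnot(inherits(testis, "testis_ellipsoid"))
  4 / 3 * pi * testis$A * testis$B * testis$C
}

# Slicing plane orientations, named by anatomical convention: the plane's
# normal is the X (long), Y (middle) or Z (short) axis respectively.
ORIENTATIONS <- c("transverse", "sagittal", "coronal")

# Map an orientation to the ratio along its normal ("r") and the two
# in-plane ratios ("p", "q"), plus the axis letter for messages.
.axis_map <- function(testis, orientation) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  switch(orientation,
    transverse = list(r = testis$a, p = testis$b, q = testis$c, axis = "x"),
    sagittal   = list(r = testis$b, p = testis$c, q = testis$a, axis = "y"),
    coronal    = list(r = testis$c, p = testis$a, q = testis$b, axis = "z")
  )
}
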