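# Ellipsoid model, cross-section areas, slice-face sums.

test_that("testis_ellipsoid validates its invariants", {
  t <- testis_ellipsoid(3, 2, 1, l = 2.5)
  expect_s3_class(t, "testis_ellipsoid")
  expect_equal(c(t$A, t$B, t$C), c(7.5, 5, 2.5))
  expect_error(testis_ellipsoid(2, 3, 1), "a >= b >= c")
  expect_error(testis_ellipsoid(3, 2, 0), "positive")
  expect_error(testis_ellipsoid(3, 2.5, 1), "strict mode requires integer")
  expect_silent(testis_ellipsoid(3, 2.5, 1, strict = FALSE))
  expect_error(testis_ellipsoid(3, 2, 1, l = -1), "positive")
})

test_that("half cross-section areas match the closed formulas and poles vanish", {
  t211 <- testis_ellipsoid(2, 1, 1)
  expect_equal(half_cross_section_area(t211, "transverse", 0), pi / 2)
  expect_equal(half_cross_section_area(t211, "transverse", 2), 0)
  t321 <- testis_ellipsoid(3, 2, 1)
  expect_equal(half_cross_section_area(t321, "sagittal", 1), 9 * pi / 8)
  # even in index, strictly decreasing in |index|
  s <- vapply(-2:2, function(i) half_cross_section_area(t321, "transverse", i), 0)
  expect_equal(s, rev(s))
  expect_true(all(diff(s[3:5]) < 0))
  expect_error(half_cross_section_area(t321, "sagittal", 3), "valid y in \\[-2, 2\\]")
})

test_that("quadrature oracle agrees with the closed-form sections", {
  t211 <- testis_ellipsoid(2, 1, 1)
  # central section is a unit circle
  expect_equal(plane_section_area_quadrature(t211, "transverse", 0, 1024), pi,
               tolerance = 1e-4)
  t321 <- testis_ellipsoid(3, 2, 1)
  expect_equal(plane_section_area_quadrature(t321, "transverse", 1, 1024),
               pi * 2 * 1 * (9 - 1) / 9, tolerance = 1e-4)
  # degenerate pole plane
  expect_lt(plane_section_area_quadrature(t321, "coronal", 1, 1024), 1e-3)
  # sampled grid, all orientations and interior indices
  for (k in seq_len(nrow(strict_triples(6)))) {
    tr <- strict_triples(6)[k, ]
    t <- testis_ellipsoid(tr$a, tr$b, tr$c, l = 1.5)
    for (o in c("transverse", "sagittal", "coronal")) {
      r <- switch(o, transverse = tr$a, sagittal = tr$b, coronal = tr$c)
      for (idx in 0:(r - 1)) {
        expect_equal(plane_section_area_quadrature(t, o, idx, 1024),
                     2 * half_cross_section_area(t, o, idx),
                     tolerance = 1e-4)
      }
    }
  }
  expect_error(plane_section_area_quadrature(t321, "transverse", 0, 32), ">= 64")
})

test_that("closed-form slice sums equal direct summation over the full grid", {
  # single central cut on the unit sphere: 4 * (pi/2) = 2*pi
  sph <- testis_ellipsoid(1, 1, 1)
  expect_equal(slice_face_sum_direct(sph, "transverse"), 2 * pi)
  expect_equal(slice_face_sum_closed(sph, "transverse"), 2 * pi)
  # term-by-term derived values
  expect_equal(slice_face_sum_direct(testis_ellipsoid(2, 1, 1), "transverse"),
               5 * pi)
  t321 <- testis_ellipsoid(3, 2, 1)
  expect_equal(slice_face_sum_direct(t321, "transverse"), 140 * pi / 9)
  expect_equal(slice_face_sum_closed(t321, "transverse"), 140 * pi / 9)
  expect_equal(slice_face_sum_closed(t321, "sagittal"), 15 * pi)
  expect_equal(slice_face_sum_direct(t321, "sagittal"), 15 * pi)
  # property: equality over all ordered triples a <= 12, three widths
  grid <- ordered_triples(12)
  for (l in c(0.5, 1, 2.5)) {
    for (k in seq_len(nrow(grid))) {
      t <- testis_ellipsoid(grid$a[k], grid$b[k], grid$c[k], l = l)
      for (o in c("transverse", "sagittal", "coronal")) {
        cl <- slice_face_sum_closed(t, o)
        expect_equal(slice_face_sum_direct(t, o), cl, tolerance = 1e-9)
      }
    }
  }
})

test_that("generalized (non-integer) mode sums the interior lattice and refuses the closed form", {
  t <- testis_ellipsoid(2.5, 1.6, 1.2, strict = FALSE)
  expect_error(slice_face_sum_closed(t, "transverse"), "strict mode")
  manual <- 4 * sum(vapply(-2:2, function(i)
    half_cross_section_area(t, "transverse", i), 0))
  expect_equal(slice_face_sum_direct(t, "transverse"), manual)
})

test_that("areas scale as l^2 and volume as l^3", {
  t1 <- testis_ellipsoid(4, 3, 2, l = 1)
  t2 <- testis_ellipsoid(4, 3, 2, l = 2.5)
  for (o in c("transverse", "sagittal", "coronal")) {
    expect_equal(slice_face_sum_closed(t2, o), 2.5^2 * slice_face_sum_closed(t1, o))
    expect_equal(half_cross_section_area(t2, o, 1),
                 2.5^2 * half_cross_section_area(t1, o, 1))
  }
  expect_equal(ellipsoid_volume(t2), 2.5^3 * ellipsoid_volume(t1))
  expect_equal(ellipsoid_volume(testis_ellipsoid(1, 1, 1)), 4 * pi / 3)
  expect_equal(ellipsoid_volume(testis_ellipsoid(3, 2, 1)), 8 * pi)
  expect_equal(ellipsoid_volume(testis_ellipsoid(3, 2, 1, l = 0.5)), pi)
})

test_that("slice-face sum times width converges to twice the volume", {
  # fixed organ 20 x 10 x 4 mm, slice width A/a with a = 10, 20, 40, 80
  errs <- vapply(c(10, 20, 40, 80), function(a) {
    t <- testis_ellipsoid(a, a / 2, a / 5, l = 20 / a)
    lim <- 2 * ellipsoid_volume(t)
    abs(slice_face_sum_direct(t, "transverse") * t$l - lim) / lim
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-4)
})
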