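# SRR arithmetic, chi-square test, cohort comparison, synthetic cohorts.

test_that("srr rounds half-up at the requested precision", {
  expect_equal(srr(46, 102), 45)
  expect_equal(srr(16, 56), 29)
  expect_equal(srr(0, 2), 0)
  expect_equal(srr(8, 9, 1), 88.9)
  expect_equal(srr(1, 8, 1), 12.5)
  expect_equal(srr(5, 11, 1), 45.5)   # 45.4545 -> half-up
  expect_equal(srr(13, 24, 1), 54.2)  # 54.1666 -> half-up (printed-table anomaly)
  for (n in c(1, 7, 102)) {
    expect_equal(srr(0, n), 0)
    expect_equal(srr(n, n), 100)
  }
  expect_error(srr(1, 0), "n = 0")
  expect_error(srr(5, 3), "successes <= n")
})

test_that("pearson_chi2 is the uncorrected test and matches a brute-force oracle", {
  # overall cohort comparison: X^2 ~ 4.14, p ~ .042
  ct <- pearson_chi2(46, 56, 16, 40)
  oracle <- chi2_oracle(46, 56, 16, 40)
  expect_equal(ct$statistic, oracle$statistic)
  expect_equal(ct$p.value, oracle$p.value)
  expect_equal(ct$p.value, 0.042, tolerance = 0.02)
  expect_lt(ct$p.value, 0.05)
  expect_equal(ct$df, 1L)
  # maturation-arrest subgroup 0/2 vs 8/9: only the UNcorrected statistic
  # gives p = .011 (Yates-corrected and Fisher p are ~ .05 or larger)
  uma <- pearson_chi2(0, 2, 8, 1)
  expect_equal(uma$statistic, chi2_oracle(0, 2, 8, 1)$statistic)
  expect_equal(uma$p.value, 0.011, tolerance = 0.05)
  expect_gt(suppressWarnings(
    stats::chisq.test(matrix(c(0, 2, 8, 1), 2, byrow = TRUE))$p.value), 0.04)
  expect_gt(stats::fisher.test(matrix(c(0, 2, 8, 1), 2, byrow = TRUE))$p.value, 0.04)
  # identical proportions
  flat <- pearson_chi2(5, 5, 5, 5)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  # invariance to swapping groups and outcome columns
  expect_equal(pearson_chi2(16, 40, 46, 56)$statistic, ct$statistic)
  expect_equal(pearson_chi2(56, 46, 40, 16)$statistic, ct$statistic)
  expect_error(pearson_chi2(0, 0, 3, 4), "degenerate")
  expect_error(pearson_chi2(-1, 2, 3, 4), "non-negative")
})

test_that("compare_cohorts reproduces the published table from the reconstruction", {
  comp <- compare_cohorts(reconstruct_cohort())
  expect_s3_class(comp, "cohort_comparison")
  ov <- comp[comp$section == "overall", ]
  expect_equal(c(ov$successes_g1, ov$n_g1, ov$successes_g2, ov$n_g2),
               c(16, 56, 46, 102))
  expect_equal(c(ov$srr_g1, ov$srr_g2), c(29, 45))
  expect_true(ov$significant)
  kl <- comp[comp$label == "Klinefelter", ]
  expect_equal(c(kl$srr_g1, kl$srr_g2), c(12.5, 45.5))
  expect_false(kl$significant)
  uma <- comp[comp$label == "uniform maturation arrest", ]
  expect_equal(uma$p.value, 0.011, tolerance = 0.05)
  expect_true(uma$significant)
  # empty-on-one-side and single-outcome rows are not computable
  dash <- comp[comp$label %in% c("AZFc deletion", "47XYY", "post-chemotherapy"), ]
  expect_true(all(is.na(dash$p.value)))
  expect_output(print(comp), "uniform maturation arrest")
  expect_error(
    compare_cohorts(transform(reconstruct_cohort(), subgroup = "XYZ")),
    "unknown etiology")
})

test_that("synth_cohort is deterministic, respects sizes, and hits edge rates", {
  spec <- published_mix_spec()
  rec1 <- synth_cohort(spec, seed = 42)
  rec2 <- synth_cohort(spec, seed = 42)
  expect_identical(rec1, rec2)
  expect_equal(nrow(rec1), 158L)
  expect_equal(as.vector(table(rec1$cohort)[c("previous", "new")]), c(56L, 102L))
  # new-cohort success count within the central 99% binomial band at p = .45
  s_new <- sum(rec1$outcome == "success" & rec1$cohort == "new")
  band <- qbinom(c(0.005, 0.995), 102, 46 / 102)
  expect_gte(s_new, band[1]); expect_lte(s_new, band[2])
  # different seed, different draw (overwhelmingly)
  expect_false(identical(synth_cohort(spec, seed = 43), rec1))
  # rate 0 -> all failures; rate 1 -> all successes
  z <- synth_cohort(data.frame(cohort = "new", subgroup = "other",
                               n = 25, rate = 0), seed = 1)
  expect_true(all(z$outcome == "failure"))
  o <- synth_cohort(data.frame(cohort = "new", subgroup = "other",
                               n = 25, rate = 1), seed = 1)
  expect_true(all(o$outcome == "success"))
  expect_equal(nrow(synth_cohort(spec[0, ], seed = 1)), 0L)
  expect_error(synth_cohort(transform(spec, rate = rate + 2), seed = 1), "\\[0, 1\\]")
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(synth_cohort(spec, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("subgroup SRRs recover the generating rates on large cohorts", {
  spec <- data.frame(cohort = rep(c("previous", "new"), each = 2),
                     subgroup = rep(c("Klinefelter", "other"), 2),
                     n = 10000, rate = c(0.2, 0.35, 0.5, 0.65))
  comp <- compare_cohorts(synth_cohort(spec, seed = 11))
  kl <- comp[comp$label == "Klinefelter", ]
  ot <- comp[comp$label == "other", ]
  # within 2 percentage points of the generating rate at n = 10^4
  expect_lt(abs(kl$srr_g1 / 100 - 0.2), 0.02)
  expect_lt(abs(kl$srr_g2 / 100 - 0.5), 0.02)
  expect_lt(abs(ot$srr_g1 / 100 - 0.35), 0.02)
  expect_lt(abs(ot$srr_g2 / 100 - 0.65), 0.02)
})

test_that("power_sim calibrates and matches pearson_chi2 per replicate", {
  # under the alternative, power exceeds the null rejection rate
  null_rate <- power_sim(56, 102, 0.29, 0.29, reps = 2000, seed = 5)
  alt_rate <- power_sim(56, 102, 0.29, 0.45, reps = 2000, seed = 5)
  expect_gt(alt_rate, null_rate)
  # all-degenerate edge: p1 = p2 = 0
  zero <- power_sim(56, 102, 0, 0, reps = 100, seed = 5)
  expect_equal(as.numeric(zero), 0)
  expect_equal(attr(zero, "n_degenerate"), 100L)
  expect_error(power_sim(56, 102, 0.3, 0.3, reps = 50, seed = 1), "at least 100")
  # vectorized statistic == pearson_chi2 on a spot check of tables
  for (tab in list(c(10, 46, 40, 62), c(3, 53, 40, 62), c(30, 26, 30, 72))) {
    s1 <- tab[1]; f1 <- tab[2]; s2 <- tab[3]; f2 <- tab[4]
    N <- sum(tab)
    vec_stat <- N * (s1 * f2 - f1 * s2)^2 /
      ((s1 + f1) * (s2 + f2) * (s1 + s2) * (f1 + f2))
    expect_equal(vec_stat, pearson_chi2(s1, f1, s2, f2)$statistic)
  }
})

test_that("patient CSV round-trips losslessly and validates rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- reconstruct_cohort()
  write_cohort_csv(rec, path)
  back <- read_cohort_csv(path)
  expect_equal(back, rec)
  bad <- rec; bad$outcome[3] <- "maybe"
  bad_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_cohort_csv(bad_path), "row 3")
  expect_error(read_cohort_csv("no-such-file.csv"), "no such file")
})
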