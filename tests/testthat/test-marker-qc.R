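test_that("CP cross configurations have standard Mendelian expectations", {
  expect_equal(cp_expected_ratios("lmxll"), c(lm = 0.5, ll = 0.5))
  expect_equal(cp_expected_ratios("hkxhk"),
               c(hh = 0.25, hk = 0.5, kk = 0.25))
  expect_equal(unname(cp_expected_ratios("abxcd")), rep(0.25, 4))
  expect_equal(unname(cp_expected_ratios("efxeg")), rep(0.25, 4))
  expect_equal(cp_expected_ratios("<nnxnp>"), c(nn = 0.5, np = 0.5))
  expect_error(cp_expected_ratios("aaxbb"), "unsupported cross type")
})

test_that("distortion test reproduces textbook chi-square values", {
  even <- distortion_test(rep(c("lm", "ll"), each = 50), "lmxll")
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  expect_false(even$distorted)

  skewed <- distortion_test(rep(c("lm", "ll"), c(80, 20)), "lmxll")
  expect_equal(skewed$chi2, 36)       # (80-50)^2/50 * 2
  expect_equal(skewed$df, 1L)
  expect_equal(skewed$p, pchisq(36, 1, lower.tail = FALSE))
  expect_true(skewed$distorted)

  hk <- distortion_test(rep(c("hh", "hk", "kk"), c(25, 50, 25)), "hkxhk")
  expect_equal(hk$chi2, 0)
  expect_equal(hk$df, 2L)

  # cross-check a non-trivial case against stats::chisq.test
  calls <- rep(c("hh", "hk", "kk"), c(30, 45, 25))
  got <- distortion_test(calls, "hkxhk")
  ref <- suppressWarnings(chisq.test(c(30, 45, 25),
                                     p = c(0.25, 0.5, 0.25)))
  expect_equal(got$chi2, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)

  # a class never observed still contributes its expectation
  absent <- distortion_test(rep(c("lm"), 40), "lmxll")
  expect_equal(absent$chi2, 40)
  expect_error(distortion_test(c("xx", "lm"), "lmxll"), "not allowed")
  expect_error(distortion_test(rep(NA_character_, 5), "lmxll"),
               "no non-missing")
})

test_that("missing calls are excluded from the test but counted in the missing fraction", {
  calls <- c(rep(c("lm", "ll"), each = 30), rep("--", 40))
  res <- distortion_test(calls, "lmxll")
  expect_equal(res$n, 60L)
  expect_equal(res$missing_frac, 0.4)
  expect_equal(res$chi2, 0)
})

test_that("marker QC flags distortion, excess missingness and null alleles", {
  sim <- sim_pedigree(n_markers = 40, n_progeny = 120,
                      distorted_frac = 0.25, distortion_shift = 0.3,
                      missing_range = c(0, 0.02), null_frac = 0.1,
                      seed = 17)
  qc <- qc_segregation(sim$seg)
  # every planted distortion is caught; undistorted markers may rarely
  # exceed the 0.005 threshold by chance
  expect_true(all(qc$distorted[sim$truth_markers$distorted]))
  expect_lte(sum(qc$distorted & !sim$truth_markers$distorted), 2L)
  expect_identical(qc$null_allele, sim$truth_markers$null_allele)
  expect_identical(qc$keep,
                   !(qc$distorted | qc$excess_missing | qc$null_allele))
  # a marker with > 70% missing is flagged regardless of segregation
  seg <- seg_data(data.frame(marker = "mk", cross_type = "lmxll"),
                  matrix(c(rep(c("lm", "ll"), 5), rep(NA, 90)), nrow = 1))
  expect_true(qc_segregation(seg)$excess_missing)
})

test_that("sample filtering drops exactly the high-missing samples and is idempotent", {
  sim <- sim_pedigree(n_markers = 100, n_progeny = 98,
                      missing_range = c(0, 0.02),
                      n_high_missing = 1, high_missing_frac = 0.41,
                      seed = 23)
  fs <- filter_samples(sim$seg$calls, threshold = 0.40)
  planted <- sim$truth_samples$sample[sim$truth_samples$planted_high_missing]
  expect_identical(sort(fs$dropped), sort(planted))
  expect_equal(length(fs$retained), 97L)
  again <- filter_samples(sim$seg$calls[, fs$retained], threshold = 0.40)
  expect_identical(again$retained, fs$retained)
  full <- filter_samples(matrix("lm", 5, 4), threshold = 0.40)
  expect_equal(length(full$retained), 4L)
})

test_that("multi-locus profiles verify sample identity and expose discrepancies", {
  prof <- matrix(c("lm", "ll", "lm", "lm", "ll", "ll"), nrow = 1,
                 dimnames = list("s1", paste0("m", 1:6)))
  same <- match_samples(prof, prof)
  expect_equal(same$concordance, 1)
  expect_true(same$matched)
  off <- prof
  off[1, 1] <- "ll"
  rownames(off) <- "s2"
  res <- match_samples(prof, off)
  expect_equal(res$concordance, 5 / 6)
  expect_false(res$matched)
  # fewer than min_loci comparable loci cannot declare a match
  short <- prof[, 1:3, drop = FALSE]
  expect_false(match_samples(short, short, min_loci = 5)$matched)
  # all-missing overlap is incomparable
  na_prof <- prof
  na_prof[] <- NA
  expect_true(is.na(match_samples(prof, na_prof)$concordance))
})

test_that("sample matcher recovers a planted label permutation across cohorts", {
  sim <- sim_pedigree(n_markers = 30, n_progeny = 60,
                      missing_range = c(0, 0.02), n_shared = 12, seed = 29)
  res <- match_samples(sim$cohort_b, t(sim$seg$calls))
  hits <- res[res$matched, ]
  expect_equal(nrow(hits), 12L)
  expect_identical(
    sim$identity$sample[match(hits$sample_a, sim$identity$label)],
    hits$sample_b)
})

test_that("loc files round-trip through the JoinMap dialect reader", {
  sim <- sim_pedigree(n_markers = 12, n_progeny = 20,
                      missing_range = c(0.05, 0.2), seed = 37)
  path <- tempfile(fileext = ".loc")
  write_loc(sim$seg, path, name = "synthpop")
  back <- read_loc(path)
  expect_identical(attr(back, "name"), "synthpop")
  expect_identical(back$markers$marker, sim$seg$markers$marker)
  expect_identical(back$markers$cross_type, sim$seg$markers$cross_type)
  expect_identical(unname(back$calls), unname(sim$seg$calls))
  # malformed records are rejected
  bad <- tempfile(fileext = ".loc")
  writeLines(c("name = x", "popt = CP", "nloc = 1", "nind = 4",
               "mk1 lm ll lm ll"), bad)
  expect_error(read_loc(bad), "malformed")
})
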