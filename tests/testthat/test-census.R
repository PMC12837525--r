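test_that("census_table derives ratio statistics and handles degenerate counts", {
  cen <- census_table(I = 10, S = 0, T = 0)
  expect_equal(cen$S_over_I, 0)
  expect_equal(cen$T_over_I, 0)
  expect_equal(cen$ST_over_I, 0)
  expect_identical(cen$STI, 10)

  # no intact elements: ratios undefined, not a division error
  cen0 <- census_table(I = 0, S = 5, T = 2)
  expect_true(is.na(cen0$S_over_I))
  expect_identical(cen0$STI, 7)

  expect_error(census_table(10, 5, 2, filtered_I = 11), "filtered")
  expect_error(census_table(-1, 0, 0), "non-negative")
})

test_that("run_census counts, filters by scaffold length, and conserves totals", {
  loci <- data.frame(
    scaffold = c("a", "a", "b", "b", "b", "c"),
    status = c("intact", "solo", "solo", "truncated", "intact", "solo"),
    stringsAsFactors = FALSE)
  slen <- c(a = 50000, b = 2000, c = 1000)

  cen <- run_census(loci, slen, min_scaffold_length = 0)
  expect_identical(cen$STI, nrow(loci))

  cen2 <- run_census(loci, slen, min_scaffold_length = 5000)
  expect_identical(cen2$filtered_I, 1L)   # only scaffold a survives
  expect_identical(cen2$filtered_S, 1L)
  expect_identical(cen2$filtered_T, 0L)
  # conservation at the filter level
  expect_identical(cen2$filtered_I + cen2$filtered_S + cen2$filtered_T,
                   sum(slen[loci$scaffold] >= 5000))

  # monotonicity: counts non-increasing in the threshold
  thresholds <- c(0, 1500, 5000, 1e5)
  counts <- sapply(thresholds, function(t) {
    cc <- run_census(loci, slen, t)
    c(cc$filtered_I, cc$filtered_S, cc$filtered_T)
  })
  expect_true(all(diff(t(counts))[, 1] <= 0))
  expect_true(all(diff(t(counts))[, 2] <= 0))

  expect_error(run_census(loci, slen[1:2]), "missing scaffolds")
})

test_that("family census flags high-elimination families, counting I=0 as eliminated", {
  loci <- rbind(
    data.frame(family = "f1", status = c(rep("solo", 8), "intact", "intact")),
    data.frame(family = "f2", status = c("solo", "intact")),
    data.frame(family = "f3", status = c("solo", "solo", "truncated")))
  fc <- family_census(loci)
  f <- fc$families
  expect_equal(f$S_over_I[f$family == "f1"], 4)      # 8/2 > 3 -> high
  expect_equal(f$S_over_I[f$family == "f2"], 1)      # not high
  expect_true(is.infinite(f$S_over_I[f$family == "f3"]))  # complete elimination
  expect_identical(f$high, c(TRUE, FALSE, TRUE))
  expect_identical(fc$n_families, 3L)
  expect_identical(fc$n_high, 2L)
  expect_equal(fc$proportion_high, 100 * 2 / 3)

  # all families at or below the threshold
  low <- data.frame(family = rep(c("f1", "f2"), each = 4),
                    status = rep(c("solo", "solo", "solo", "intact"), 2))
  expect_identical(family_census(low)$n_high, 0L)
  expect_equal(family_census(low)$proportion_high, 0)

  expect_identical(family_census(loci[0, ])$n_families, 0L)
})

test_that("stability scan finds where short-scaffold solo inflation dies out", {
  # small scaffolds (1-3 kb) carry only solo LTRs; large scaffolds carry a
  # balanced census
  small <- data.frame(
    scaffold = sprintf("small%02d", 1:40), status = "solo",
    stringsAsFactors = FALSE)
  big <- data.frame(
    scaffold = rep(sprintf("big%02d", 1:10), each = 6),
    status = rep(c("intact", "intact", "solo", "solo", "solo", "truncated"), 10),
    stringsAsFactors = FALSE)
  loci <- rbind(small, big)
  slen <- c(setNames(rep(c(1000, 2000, 3000), length.out = 40),
                     sprintf("small%02d", 1:40)),
            setNames(seq(50000, 95000, by = 5000), sprintf("big%02d", 1:10)))

  scan <- stability_scan(loci, slen,
                         grid = c(0, 1000, 2000, 3000, 5000, 50000, 80000),
                         tolerance = 0.01, patience = 2)

  # oracle: recompute S:I by direct filtering at every grid threshold
  for (i in seq_len(nrow(scan$scan))) {
    keep <- slen[loci$scaffold] >= scan$scan$threshold[i]
    sub <- loci[keep, ]
    expect_equal(scan$scan$S_over_I[i],
                 sum(sub$status == "solo") / sum(sub$status == "intact"))
  }

  expect_true(scan$stable)
  expect_gt(scan$selected_threshold, 3000)   # beyond the small-scaffold mode
  filt <- scan$scan$S_over_I[scan$scan$threshold == scan$selected_threshold]
  expect_lt(filt, scan$scan$S_over_I[1])     # filtering lowers S:I

  # all loci on one long scaffold: ratio constant, first grid point selected
  one <- data.frame(scaffold = "chr1",
                    status = rep(c("intact", "solo"), 10))
  scan1 <- stability_scan(one, c(chr1 = 1e6),
                          grid = c(0, 1e3, 1e4, 1e5))
  expect_identical(scan1$selected_threshold, 0)
  expect_true(scan1$stable)

  # single-point grid
  expect_identical(stability_scan(one, c(chr1 = 1e6),
                                  grid = 0)$selected_threshold, 0)

  expect_error(stability_scan(one, c(chr1 = 1e6), grid = c(10, 20)), "grid")
  expect_error(stability_scan(one, c(chr1 = 1e6), grid = 0, tolerance = 0),
               "tolerance")
})

test_that("scan truncates with a flag when a threshold removes all intact loci", {
  loci <- data.frame(scaffold = c("a", "a", "b"),
                     status = c("intact", "solo", "solo"))
  slen <- c(a = 1000, b = 50000)
  scan <- stability_scan(loci, slen, grid = c(0, 2000, 60000))
  expect_true(scan$truncated)
  expect_lt(max(scan$scan$threshold), 2000)
})
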