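toy_regions <- function() {
  data.frame(scaffold = "s1",
             start = c(150, 200, 500),
             end = c(250, 300, 700),
             class = c("SPE", "SPE", "SYN"),
             stringsAsFactors = FALSE)
}

test_that("overlap_count respects half-open semantics and matches brute force", {
  reg <- normalize_regions(toy_regions())
  iv <- data.frame(scaffold = "s1", start = 100, end = 200)
  expect_identical(overlap_count(iv, reg, "SPE"), 1L)

  # [100,200) abuts [200,300): no overlap under half-open coordinates
  iv2 <- data.frame(scaffold = "s1", start = 100, end = 150)
  expect_identical(overlap_count(iv2, reg, "SPE"), 0L)

  expect_error(overlap_count(iv, reg, "INV"), "unknown region class")

  # random toy instance vs quadratic all-pairs oracle
  set.seed(41)
  reg2 <- normalize_regions(data.frame(
    scaffold = sample(c("s1", "s2"), 30, TRUE),
    start = s <- sample.int(19000, 30), end = s + sample.int(800, 30),
    class = "SPE"))
  iv3 <- data.frame(scaffold = sample(c("s1", "s2"), 50, TRUE),
                    start = s2 <- sample.int(19500, 50),
                    end = s2 + sample.int(400, 50))
  expect_identical(overlap_count(iv3, reg2, "SPE"),
                   brute_overlap_count(iv3, reg2[reg2$class == "SPE", ]))
})

test_that("normalize_regions merges within a class only", {
  reg <- normalize_regions(toy_regions())
  spe <- reg[reg$class == "SPE", ]
  expect_identical(nrow(spe), 1L)      # [150,250) + [200,300) -> [150,300)
  expect_identical(spe$start, 150L)
  expect_identical(spe$end, 300L)
  expect_identical(nrow(reg[reg$class == "SYN", ]), 1L)
})

test_that("randomize_intervals preserves lengths and weights scaffolds by size", {
  iv <- data.frame(scaffold = "a", start = c(0, 100, 500),
                   end = c(100, 350, 520))
  slen <- c(a = 10000, b = 30000)
  r1 <- randomize_intervals(iv, slen, seed = 5)
  expect_identical(randomize_intervals(iv, slen, seed = 5), r1)
  expect_equal(sort(r1$end - r1$start), sort(iv$end - iv$start))
  expect_true(all(r1$start >= 0 & r1$end <= slen[r1$scaffold]))

  # binomial oracle: one 100 bp interval drawn 2000 times lands on the
  # 30 kb scaffold with probability 0.75
  one <- data.frame(scaffold = "a", start = 0, end = 100)
  draws <- randomize_intervals(one[rep(1, 2000), ], slen, seed = 6)
  phat <- mean(draws$scaffold == "b")
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / 2000))

  big <- data.frame(scaffold = "a", start = 0, end = 50000)
  expect_error(randomize_intervals(big, slen), "longer than every scaffold")
})

test_that("permutation test is deterministic, saturates on full coverage, and is additive", {
  slen <- c(s1 = 20000)
  full <- data.frame(scaffold = "s1", start = 0, end = 20000, class = "SPE")
  set.seed(43)
  iv <- data.frame(scaffold = "s1", start = s <- sample.int(19500, 40),
                   end = s + 100)
  ot <- permutation_enrichment(iv, full, "SPE", slen, n_perm = 99, seed = 2)
  expect_identical(ot$observed, 40L)
  expect_equal(ot$p_enrich, 1)          # every null sample ties
  expect_true(is.na(ot$z_score))        # degenerate null, flagged not crashed

  ot2 <- permutation_enrichment(iv, full, "SPE", slen, n_perm = 99, seed = 2)
  expect_identical(ot2$null_samples, ot$null_samples)

  expect_error(permutation_enrichment(iv, full, "SPE", slen, n_perm = 50),
               "n_perm")

  # additivity of counts over disjoint classes for intervals hitting one class
  reg <- data.frame(scaffold = "s1", start = c(0, 10000),
                    end = c(5000, 15000), class = c("SPE", "SYN"))
  reg <- normalize_regions(reg)
  iv2 <- data.frame(scaffold = "s1",
                    start = c(100, 4800, 10100, 16000),
                    end = c(200, 4900, 10200, 16100))
  both <- rbind(reg, data.frame(scaffold = "s1", start = c(0, 10000),
                                end = c(5000, 15000), class = "union"))
  expect_identical(overlap_count(iv2, reg, "SPE") +
                     overlap_count(iv2, reg, "SYN"),
                   overlap_count(iv2, both, "union"))
})

test_that("class_coverage computes base-wise coverage with idempotent overlaps", {
  reg <- data.frame(scaffold = "s1", start = 1000, end = 2000, class = "SPE")
  one <- data.frame(scaffold = "s1", start = 1200, end = 1300)
  cov1 <- class_coverage(reg, one)
  expect_equal(cov1$percent[cov1$group == "all"], 10)

  # two LTRs covering the same 100 bp still give 10% (coverage, not sums)
  two <- rbind(one, data.frame(scaffold = "s1", start = 1250, end = 1300))
  cov2 <- class_coverage(reg, two)
  expect_equal(cov2$percent[cov2$group == "all"], 10)

  # random toy vs per-base oracle
  set.seed(47)
  regs <- data.frame(scaffold = "s1", start = c(0, 3000), end = c(2000, 4000),
                     class = "SYN")
  ivs <- data.frame(scaffold = "s1", start = s <- sample.int(3800, 25),
                    end = pmin(4200, s + sample.int(300, 25)))
  got <- class_coverage(regs, ivs)
  expect_equal(got$percent[got$group == "all"],
               brute_coverage_percent(normalize_regions(regs), ivs))

  # empty class reported as undefined, and superfamily breakdown present
  ivs$superfamily <- rep(c("Gypsy", "Copia"), length.out = 25)
  got2 <- class_coverage(regs, ivs)
  expect_true(all(c("Gypsy", "Copia") %in% got2$group))
})
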