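test_that("mutate_sequence plants exact transition/transversion counts", {
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")

  expect_identical(mutate_sequence(seq, 0, 0), seq)

  mut <- mutate_sequence(seq, 0.10, 0.05, seed = 1)
  expect_identical(nchar(mut), nchar(seq))
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(mut, "")[[1]]
  classes <- mapply(sub_class, a, b)          # brute-force column classifier
  expect_identical(sum(classes == "transition"), 100L)
  expect_identical(sum(classes == "transversion"), 50L)

  # determinism under a fixed seed
  expect_identical(mutate_sequence(seq, 0.10, 0.05, seed = 1), mut)

  expect_error(mutate_sequence(substr(seq, 1, 10), 0.5, 0.5), "P \\+ Q")
  expect_error(mutate_sequence("ACGTN", 0.1, 0), "non-ACGT")
})

test_that("simulate_genome conserves counts, determinism, and containment", {
  b <- small_bundle()
  cfg <- b$config
  expect_identical(sum(b$truth$status == "intact"), as.integer(cfg$n_intact))
  expect_identical(sum(b$truth$status == "solo"), as.integer(cfg$n_solo))
  expect_identical(sum(b$truth$status == "truncated"),
                   as.integer(cfg$n_truncated))

  # every planted interval lies within its scaffold, half-open and valid
  len <- b$scaffold_lengths[b$truth$scaffold]
  expect_true(all(b$truth$start >= 0 & b$truth$end <= len &
                    b$truth$start < b$truth$end))

  # same config, same seed: byte-identical scaffolds and truth
  b2 <- simulate_genome(cfg)
  expect_identical(b2$scaffolds, b$scaffolds)
  expect_identical(b2$truth, b$truth)

  # different seed: different placements
  cfg3 <- cfg; cfg3$seed <- 12L
  b3 <- simulate_genome(cfg3)
  expect_false(identical(b3$truth$start, b$truth$start))
})

test_that("zero divergence targets give identical LTR pairs", {
  cfg <- sim_config(n_scaffolds = 4,
                    scaffold_length_law = list(min = 2e4, max = 5e4, shape = 1.8),
                    n_intact = 4, n_solo = 0, n_truncated = 0, n_families = 2,
                    divergence_targets = data.frame(P = rep(0, 4), Q = rep(0, 4)),
                    seed = 3)
  b <- simulate_genome(cfg)
  ann <- b$intact_annotation
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    ltr5 <- substr(b$scaffolds[[r$scaffold]], r$ltr5_start + 1, r$ltr5_end)
    ltr3 <- substr(b$scaffolds[[r$scaffold]], r$ltr3_start + 1, r$ltr3_end)
    expect_identical(ltr5, ltr3)
  }
})

test_that("oversubscribed configurations raise a capacity error", {
  cfg <- sim_config(n_scaffolds = 2,
                    scaffold_length_law = list(min = 2e4, max = 2e4, shape = 1),
                    n_intact = 50, n_solo = 100, n_truncated = 30, seed = 1)
  expect_error(simulate_genome(cfg), "exceed")
})

test_that("simulate_regions realizes class fractions and rejects bad input", {
  fr <- c(INV = 0.1, SPE = 0.4, SYN = 0.4)
  slen <- c(chr1 = 1000000L)
  reg <- simulate_regions(slen, fr, seed = 5)
  base <- tapply(reg$end - reg$start, reg$class, sum)
  expect_true(abs(base[["INV"]] / 1e6 - 0.1) < 0.02)
  expect_true(abs(base[["SPE"]] / 1e6 - 0.4) < 0.02)
  expect_true(abs(base[["SYN"]] / 1e6 - 0.4) < 0.02)

  # intervals within each class are disjoint
  for (cl in names(fr)) {
    r <- reg[reg$class == cl, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }

  expect_error(simulate_regions(slen, c(INV = 0.4, SPE = 0.4, SYN = 0.4)),
               "sum")
})

test_that("placement bias scales planted LTR density with class weight", {
  cfg <- sim_config(
    n_scaffolds = 30,
    scaffold_length_law = list(min = 8e4, max = 2e5, shape = 1.2),
    n_intact = 0, n_solo = 300, n_truncated = 0, n_families = 2,
    region_fractions = c(INV = 0.05, SPE = 0.4, SYN = 0.4),
    ltr_placement_bias = c(SPE = 3, SYN = 1), min_gap = 1000,
    seed = 17)
  b <- simulate_genome(cfg)
  reg <- b$regions
  mid <- (b$truth$start + b$truth$end) / 2
  cls <- vapply(seq_len(nrow(b$truth)), function(i) {
    r <- reg[reg$scaffold == b$truth$scaffold[i] &
               reg$start <= mid[i] & reg$end > mid[i], ]
    if (nrow(r)) r$class[1] else "none"
  }, "")
  n_spe <- sum(cls == "SPE"); n_syn <- sum(cls == "SYN")
  m <- n_spe + n_syn
  # binomial oracle: SPE share of SPE+SYN placements should be 3/4 since the
  # two classes hold equal base totals; accept within 3 binomial SD
  phat <- n_spe / m
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / m))
})

test_that("gene-set simulator plants TD/PD truth and threshold-straddling pseudogenes", {
  cfg <- sim_config(td_clusters = 4, pd_clusters = 5, pseudogene_count = 20,
                    seed = 9)
  gs <- simulate_gene_set(cfg)
  expect_identical(sum(gs$pairs$true_type == "TD"), 4L)
  expect_identical(sum(gs$pairs$true_type == "PD"), 5L)
  expect_true(all(gs$pairs$intervening[gs$pairs$true_type == "TD"] == 0))
  expect_true(all(gs$pairs$intervening[gs$pairs$true_type == "PD"] %in% 1:10))
  # a pair with exactly 10 intervening genes is PD truth; 11 is not
  expect_true(any(gs$pairs$intervening == 10 & gs$pairs$true_type == "PD"))
  expect_true(any(gs$pairs$intervening == 11 & gs$pairs$true_type == "none"))
  # pseudogene truth honors strict > thresholds, incl. planted boundaries
  ps <- gs$pseudogenes
  expect_identical(ps$true_kept, ps$identity > 30 & ps$coverage > 50)
  expect_true(any(ps$identity == 30))   # exactly-at-threshold case planted
  expect_true(any(ps$coverage == 50))
  expect_false(any(ps$true_kept[ps$identity <= 30 | ps$coverage <= 50]))
})

test_that("expression simulator honors stages, seed and planted effect", {
  cfg <- sim_config(seed = 4)
  gs <- simulate_gene_set(cfg)
  ex <- simulate_expression(gs$genes, effect = 0, stages = 5, seed = 2)
  expect_identical(names(ex), c("gene_id", paste0("stage_", 1:5)))
  expect_identical(simulate_expression(gs$genes, effect = 0, stages = 5,
                                       seed = 2), ex)

  # sample-mean oracle: with 500 genes per group and effect -1 the observed
  # log2 group difference is -1 within 3 standard errors
  genes <- data.frame(gene_id = sprintf("g%d", 1:1000),
                      region_class = rep(c("SPE", "SYN"), each = 500))
  ex2 <- simulate_expression(genes, effect = -1, stages = 1, seed = 8)
  y <- log2(ex2$stage_1)
  d <- mean(y[genes$region_class == "SPE"]) -
    mean(y[genes$region_class == "SYN"])
  se <- sqrt(var(y[genes$region_class == "SPE"]) / 500 +
               var(y[genes$region_class == "SYN"]) / 500)
  expect_lt(abs(d - (-1)), 3 * se)
})
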