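toy_genes <- function() {
  data.frame(gene_id = sprintf("g%d", 1:6),
             scaffold = c("c1", "c1", "c1", "c1", "c2", "c2"),
             start = c(10, 500, 900, 500, 40, 10),
             end = c(200, 700, 1100, 600, 140, 100),
             strand = c("+", "+", "-", "+", "+", "-"),
             stringsAsFactors = FALSE)
}

test_that("rank_genes orders by start, breaks ties by end, and is order-invariant", {
  g <- toy_genes()
  r <- rank_genes(g)
  c1 <- r[r$scaffold == "c1", ]
  expect_identical(c1$gene_id, c("g1", "g4", "g2", "g3"))  # 500/600 before 500/700
  expect_identical(c1$rank, 1:4)
  expect_identical(r$rank[r$scaffold == "c2"], 1:2)

  # shuffled input gives the identical ranking
  set.seed(3)
  r2 <- rank_genes(g[sample.int(nrow(g)), ])
  expect_identical(r2, r)

  dup <- rbind(g, g[1, ])
  expect_error(rank_genes(dup), "duplicate gene_id")
})

test_that("duplication classes follow intervening-gene counts with strict boundaries", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), scaffold = "c1",
                      start = (1:20) * 1000, end = (1:20) * 1000 + 500,
                      stringsAsFactors = FALSE)
  ranked <- rank_genes(genes)
  pairs <- data.frame(
    gene_a = c("g04", "g04", "g04", "g04"),
    gene_b = c("g05", "g10", "g15", "g16"),
    stringsAsFactors = FALSE)
  calls <- classify_duplications(pairs, ranked)
  expect_identical(calls$type, c("TD", "PD", "PD", "none"))
  expect_identical(calls$intervening, c(0L, 5L, 10L, 11L))

  # symmetric in pair order
  rev_pairs <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a)
  expect_identical(classify_duplications(rev_pairs, ranked)$type, calls$type)

  # different scaffolds are never TD/PD
  g2 <- rbind(genes, data.frame(gene_id = "h01", scaffold = "c2",
                                start = 1000, end = 1500))
  cross <- classify_duplications(
    data.frame(gene_a = "g04", gene_b = "h01"), rank_genes(g2))
  expect_identical(cross$type, "none")
  expect_true(is.na(cross$intervening))

  expect_error(classify_duplications(
    data.frame(gene_a = "g04", gene_b = "nope"), ranked), "nope")
})

test_that("pseudogene filter keeps strict > 30 identity and > 50 coverage, idempotently", {
  cand <- data.frame(pseudo_id = sprintf("p%d", 1:5),
                     identity = c(31, 30, 80, 29, 45),
                     coverage = c(60, 90, 50, 90, 51))
  kept <- filter_pseudogenes(cand)
  expect_identical(kept$pseudo_id, c("p1", "p5"))
  expect_identical(filter_pseudogenes(kept), kept)

  expect_error(filter_pseudogenes(cand[, "pseudo_id", drop = FALSE]),
               "identity and coverage")
  cand$identity[1] <- NA
  expect_error(filter_pseudogenes(cand), "missing")
})

test_that("TD/PD calls recover the planted gene-set truth exactly", {
  gs <- simulate_gene_set(sim_config(td_clusters = 6, pd_clusters = 6,
                                     seed = 31))
  ranked <- rank_genes(gs$genes)
  calls <- classify_duplications(gs$pairs[, c("gene_a", "gene_b")], ranked)
  expect_identical(calls$type, gs$pairs$true_type)
  expect_identical(calls$intervening, as.integer(gs$pairs$intervening))

  kept <- filter_pseudogenes(gs$pseudogenes)
  expect_identical(sort(kept$pseudo_id),
                   sort(gs$pseudogenes$pseudo_id[gs$pseudogenes$true_kept]))
})

test_that("nearest_ltr_context reports sides strand-aware against a hand oracle", {
  genes <- data.frame(gene_id = c("gA", "gB"), scaffold = "c1",
                      start = c(10000, 30000), end = c(12000, 32000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  ltrs <- data.frame(
    element_id = sprintf("L%d", 1:6), scaffold = "c1",
    start = c(9000, 10500, 12400, 29000, 32100, 50000),
    end   = c(9500, 10800, 12900, 29400, 32500, 50400),
    stringsAsFactors = FALSE)
  ctx <- nearest_ltr_context(genes, ltrs, window = 1000)

  gA <- ctx[ctx$gene_id == "gA", ]
  # hand enumeration: L1 ends 500 bp before gA start (+ strand -> upstream),
  # L2 overlaps, L3 starts 400 bp after gA end -> downstream; L6 beyond window
  expect_identical(gA$element_id, c("L1", "L2", "L3"))
  expect_identical(gA$side, c("upstream", "overlapping", "downstream"))
  expect_equal(gA$distance, c(500, 0, 400))

  gB <- ctx[ctx$gene_id == "gB", ]
  # gB is minus-strand: L4 (left of gene) is downstream, L5 (right) upstream
  expect_identical(sort(gB$element_id), c("L4", "L5"))
  expect_identical(gB$side[gB$element_id == "L4"], "downstream")
  expect_identical(gB$side[gB$element_id == "L5"], "upstream")
  expect_equal(gB$distance[gB$element_id == "L4"], 600)

  # LTR fully inside the gene: overlapping at distance 0
  inside <- data.frame(element_id = "L7", scaffold = "c1", start = 10100,
                       end = 10200)
  ctx2 <- nearest_ltr_context(genes[1, ], inside, window = 0)
  expect_identical(ctx2$side, "overlapping")
  expect_equal(ctx2$distance, 0)

  expect_error(nearest_ltr_context(genes, ltrs, window = -1), "window")
})
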