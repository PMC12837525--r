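# Shared fixtures and independent oracles.

# compact bundle used by several suites (built once per test run)
small_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) {
      cfg <- sim_config(
        n_scaffolds = 8,
        scaffold_length_law = list(min = 2e4, max = 8e4, shape = 1.8),
        n_intact = 6, n_solo = 12, n_truncated = 4, n_families = 3,
        seed = 11)
      b <<- simulate_genome(cfg)
    }
    b
  }
})

# match each planted element to the called locus overlapping it; returns the
# called status per truth row ("missing"/"multiple" when 0 or >1 loci match)
match_truth <- function(loci, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    l <- loci[loci$scaffold == truth$scaffold[i] &
                loci$start < truth$end[i] & loci$end > truth$start[i], ]
    if (nrow(l) == 1) l$status
    else if (nrow(l) == 0) "missing" else "multiple"
  }, "")
}

# brute-force oracle: count intervals overlapping >= 1 bp with any region
brute_overlap_count <- function(intervals, regions) {
  n <- 0L
  for (i in seq_len(nrow(intervals)))
    for (j in seq_len(nrow(regions)))
      if (intervals$scaffold[i] == regions$scaffold[j] &&
          intervals$start[i] < regions$end[j] &&
          intervals$end[i] > regions$start[j]) {
        n <- n + 1L
        break
      }
  n
}

# brute-force per-base coverage oracle (percent of class bases covered)
brute_coverage_percent <- function(regions, intervals) {
  covered <- 0L; total <- 0L
  for (j in seq_len(nrow(regions))) {
    for (pos in seq(regions$start[j], regions$end[j] - 1L)) {
      total <- total + 1L
      hit <- any(intervals$scaffold == regions$scaffold[j] &
                   intervals$start <= pos & intervals$end > pos)
      if (hit) covered <- covered + 1L
    }
  }
  100 * covered / total
}

# classify the substitution between two aligned bases
sub_class <- function(a, b) {
  pur <- c("A", "G")
  if (a == b) "same"
  else if ((a %in% pur) == (b %in% pur)) "transition"
  else "transversion"
}

# independent local-homology oracle via Biostrings: does `flank` contain a
# local alignment to `ref` with >= min_len columns at >= min_id identity?
oracle_flank_hit <- function(ref, flank, min_id = 0.8, min_len = 100) {
  if (nchar(flank) < min_len) return(FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (s in c(flank, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(flank))))) {
    aln <- Biostrings::pairwiseAlignment(ref, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    w <- Biostrings::nchar(aln)
    if (w >= min_len && Biostrings::pid(aln) / 100 >= min_id) return(TRUE)
  }
  FALSE
}
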