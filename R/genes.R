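# Positional gene-duplication classes (tandem / proximal), pseudogene
# filtering, and LTR context around genes.

#' Rank genes along their scaffolds
#'
#' Orders genes by start (ties broken by end, then gene_id) and assigns
#' consecutive ranks 1..n per scaffold. The ranking is invariant to input
#' order.
#'
#' @param genes data.frame: gene_id, scaffold, start, end (overlapping genes
#'   permitted).
#' @return the input with a `rank` column, sorted by scaffold and rank.
#' @export
rank_genes <- function(genes) {
  check_intervals(genes, "genes")
  if (anyDuplicated(genes$gene_id))
    stop_input("duplicate gene_id: %s",
               genes$gene_id[anyDuplicated(genes$gene_id)])
  ord <- order(genes$scaffold, genes$start, genes$end, genes$gene_id)
  out <- genes[ord, , drop = FALSE]
  out$rank <- as.integer(ave(seq_len(nrow(out)), out$scaffold,
                             FUN = function(i) seq_along(i)))
  rownames(out) <- NULL
  out
}

#' Classify homologous gene pairs as tandem or proximal duplications
#'
#' A pair of homologous genes on the same scaffold is a tandem duplication
#' (TD) when the genes are physically adjacent (0 intervening genes) and a
#' proximal duplication (PD) when separated by 1 to `max_proximal`
#' intervening genes; anything else (including pairs on different
#' scaffolds) is "none". Adjacency is purely positional, irrespective of
#' strand. The call is symmetric in pair order.
#'
#' @param pairs data.frame: gene_a, gene_b.
#' @param ranked_genes output of [rank_genes()].
#' @param max_proximal largest intervening-gene count still called PD.
#' @return data.frame: gene_a, gene_b, intervening (NA across scaffolds),
#'   type in {TD, PD, none}.
#' @export
classify_duplications <- function(pairs, ranked_genes, max_proximal = 10) {
  idx <- match(pairs$gene_a, ranked_genes$gene_id)
  idx2 <- match(pairs$gene_b, ranked_genes$gene_id)
  bad <- c(pairs$gene_a[is.na(idx)], pairs$gene_b[is.na(idx2)])
  if (length(bad))
    stop_input("unknown gene id in pairs: %s", paste(bad, collapse = ", "))
  same <- ranked_genes$scaffold[idx] == ranked_genes$scaffold[idx2]
  intervening <- as.integer(ifelse(same,
                        abs(ranked_genes$rank[idx] - ranked_genes$rank[idx2]) - 1L,
                        NA_integer_))
  type <- ifelse(!same, "none",
          ifelse(intervening == 0L, "TD",
          ifelse(intervening >= 1L & intervening <= max_proximal, "PD",
                 "none")))
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             intervening = intervening, type = type,
             stringsAsFactors = FALSE)
}

#' Filter pseudogene candidates
#'
#' Keeps candidates whose amino-acid identity to the parent gene exceeds
#' `min_identity` percent and whose parent alignment covers more than
#' `min_coverage` percent of the pseudogene. Both thresholds are strict
#' (a candidate at exactly 30% identity or 50% coverage is removed). The
#' filter is idempotent.
#'
#' @param candidates data.frame with numeric `identity` and `coverage`
#'   columns in percent.
#' @param min_identity,min_coverage strict lower thresholds in percent.
#' @return the surviving rows.
#' @export
filter_pseudogenes <- function(candidates, min_identity = 30,
                               min_coverage = 50) {
  need <- c("identity", "coverage")
  if (!all(need %in% names(candidates)))
    stop_input("candidates must have identity and coverage columns")
  if (anyNA(candidates$identity) || anyNA(candidates$coverage))
    stop_input("identity/coverage must not contain missing values")
  keep <- candidates$identity > min_identity &
    candidates$coverage > min_coverage
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report LTR-RT elements near each gene
#'
#' For every gene, lists LTR loci overlapping it or lying within `window`
#' bp of it. Sides are reported relative to gene orientation: for a minus-
#' strand gene, an element right of the gene end is upstream. Distance is
#' the gap in bp (0 for overlaps).
#'
#' @param genes data.frame: gene_id, scaffold, start, end, strand.
#' @param ltr_loci data.frame: element_id, scaffold, start, end.
#' @param window search distance in bp on each side (>= 0).
#' @return data.frame: gene_id, element_id, side in
#'   {upstream, overlapping, downstream}, distance.
#' @export
nearest_ltr_context <- function(genes, ltr_loci, window = 10000) {
  if (window < 0) stop_input("window must be >= 0")
  check_intervals(genes, "genes")
  check_intervals(ltr_loci, "ltr_loci")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    l <- ltr_loci[ltr_loci$scaffold == g$scaffold, , drop = FALSE]
    if (!nrow(l)) next
    overl <- l$start < g$end & l$end > g$start
    left <- !overl & l$end <= g$start & g$start - l$end <= window
    right <- !overl & l$start >= g$end & l$start - g$end <= window
    dist <- rep(NA_real_, nrow(l))
    dist[overl] <- 0
    dist[left] <- g$start - l$end[left]
    dist[right] <- l$start[right] - g$end
    side <- rep(NA_character_, nrow(l))
    side[overl] <- "overlapping"
    minus <- identical(g$strand, "-")
    side[left] <- if (minus) "downstream" else "upstream"
    side[right] <- if (minus) "upstream" else "downstream"
    keep <- overl | left | right
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, element_id = l$element_id[keep],
        side = side[keep], distance = dist[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), element_id = character(0),
                      side = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
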