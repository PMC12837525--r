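# Seed-and-extend nucleotide homology search and flanking-homology
# classification of LTR-RT loci into solo / truncated / intact-overlap.

#' Search scaffolds for local homology to a query
#'
#' Seed-and-extend local search: exact `word_size`-mers seed ungapped
#' X-drop extensions, trimmed to the maximal-scoring extent. Both strands are
#' searched (the reverse complement of the query is matched against the
#' forward subject). Overlapping hits on the same strand are merged, keeping
#' the extent of the higher-identity hit.
#'
#' @param query nucleotide string (length >= `word_size`).
#' @param scaffolds named character vector of subject sequences.
#' @param min_identity minimum fraction identity over the hit extent.
#' @param min_length minimum hit length in bp.
#' @param word_size exact seed length.
#' @param query_id label recorded in the output.
#' @param xdrop score drop-off terminating extension (+1 match / -2 mismatch
#'   scoring).
#' @return data.frame: query_id, scaffold, start, end (0-based half-open,
#'   subject coordinates), strand, identity, aligned_length.
#' @export
search_homology <- function(query, scaffolds, min_identity = 0.8,
                            min_length = 100, word_size = 11,
                            query_id = "query", xdrop = 20) {
  query <- check_dna(query, "query")
  if (min_identity <= 0 || min_identity > 1)
    stop_input("min_identity must be in (0, 1]")
  if (min_length < 1 || word_size < 4)
    stop_input("min_length must be >= 1 and word_size >= 4")
  if (nchar(query) < word_size)
    stop_input("query (%d bp) shorter than word_size (%d)", nchar(query),
               word_size)
  hits <- multi_query_search(
    scaffolds,
    queries = c(query, revcomp(query)),
    strands = c("+", "-"),
    query_ids = c(query_id, query_id),
    min_identity = min_identity, min_length = min_length,
    word_size = word_size, xdrop = xdrop)
  merge_hits(hits)
}

# run seed_extend_cpp for a set of oriented queries over every scaffold
multi_query_search <- function(scaffolds, queries, strands, query_ids,
                               min_identity, min_length, word_size, xdrop) {
  out <- list()
  for (sc in names(scaffolds)) {
    h <- seed_extend_cpp(scaffolds[[sc]], queries, as.integer(word_size),
                         min_identity, as.integer(min_length), xdrop)
    if (!nrow(h)) next
    out[[length(out) + 1L]] <- data.frame(
      query_id = query_ids[h$query], scaffold = sc, start = h$start,
      end = h$end, strand = strands[h$query], identity = h$identity,
      aligned_length = h$aligned_length, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_hits <- function() {
  data.frame(query_id = character(0), scaffold = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             identity = numeric(0), aligned_length = integer(0),
             stringsAsFactors = FALSE)
}

# greedy non-overlap selection by descending identity within scaffold+strand:
# of two overlapping hits the higher-identity extent survives
merge_hits <- function(hits, by_strand = TRUE) {
  if (!nrow(hits)) return(hits)
  key <- if (by_strand) paste(hits$scaffold, hits$strand) else hits$scaffold
  keep <- logical(nrow(hits))
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(-hits$identity[idx], -hits$aligned_length[idx])]
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in idx) {
      if (!any(hits$start[i] < taken_e & hits$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, hits$start[i])
        taken_e <- c(taken_e, hits$end[i])
      }
    }
  }
  res <- hits[keep, , drop = FALSE]
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify one LTR homology hit by flanking internal homology
#'
#' Searches the `flank_window` bp immediately upstream and downstream of a
#' candidate LTR hit for homology to the family's internal (Gag-Pol)
#' reference. No internal homology on either side means the LTR stands alone
#' (solo); homology on exactly one side means a truncated element; homology
#' on both sides indicates the hit sits between the two LTRs of an intact
#' element and is returned as "intact-overlap" for the caller to reconcile
#' rather than silently dropped. Flanks are clipped at scaffold ends.
#'
#' @param hit one-row data.frame with scaffold, start, end (0-based
#'   half-open).
#' @param internal_reference internal-domain nucleotide reference.
#' @param scaffolds named character vector of scaffold sequences.
#' @param flank_window flank length in bp to scan on each side.
#' @param min_identity,min_length,word_size search parameters passed to
#'   [search_homology()].
#' @return one of "solo", "truncated", "intact-overlap".
#' @export
classify_locus <- function(hit, internal_reference, scaffolds,
                           flank_window = NULL, min_identity = 0.8,
                           min_length = 100, word_size = 11) {
  internal_reference <- check_dna(internal_reference, "internal_reference")
  if (is.null(flank_window))
    flank_window <- default_flank_window(nchar(internal_reference))
  if (flank_window <= 0) stop_input("flank_window must be > 0")
  seq <- scaffolds[[hit$scaffold]]
  L <- nchar(seq)
  up_s <- max(0L, hit$start - flank_window)
  dn_e <- min(L, hit$end + flank_window)
  side_hit <- function(s, e) {
    if (e - s < min(min_length, word_size)) return(FALSE)
    flank <- setNames(substr(seq, s + 1L, e), "flank")
    h <- search_homology(internal_reference, flank,
                         min_identity = min_identity,
                         min_length = min(min_length, e - s),
                         word_size = word_size)
    nrow(h) > 0
  }
  up <- side_hit(up_s, hit$start)
  dn <- side_hit(hit$end, dn_e)
  if (up && dn) "intact-overlap" else if (up || dn) "truncated" else "solo"
}

# flank window: 1.5x the internal reference, capped at 15 kb
default_flank_window <- function(internal_length) {
  min(15000L, as.integer(ceiling(1.5 * internal_length)))
}

#' Classify all LTR-RT loci of a genome
#'
#' End-to-end flanking-homology classification. Intact elements (with 5'/3'
#' LTR and internal coordinates) are taken from the input annotation, as
#' produced by structure-aware de novo annotators. Their 5' LTR and internal
#' sequences provide per-family references; each family's LTR reference is
#' then searched against the whole genome, hits overlapping annotated intact
#' elements are excluded (so an intact element's own LTRs are never counted
#' again), overlapping hits across families are resolved to the
#' highest-identity family, and every remaining LTR locus is classified with
#' [classify_locus()].
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param intact_annotation data.frame with one row per intact element:
#'   element_id, scaffold, start, end, strand, family, superfamily,
#'   ltr5_start/ltr5_end, internal_start/internal_end, ltr3_start/ltr3_end
#'   (0-based half-open).
#' @param min_identity,min_length,word_size homology-search parameters.
#' @param flank_window flank scan width; default 1.5x internal reference
#'   length, capped at 15 kb.
#' @param keep_intact_overlap keep loci classified "intact-overlap" in the
#'   output (default TRUE; they are flagged, not dropped).
#' @return data.frame of LTR-RT loci: element_id, scaffold, start, end,
#'   strand, family, superfamily, status in
#'   {intact, solo, truncated, intact-overlap}.
#' @export
classify_genome <- function(scaffolds, intact_annotation,
                            min_identity = 0.8, min_length = 100,
                            word_size = 11, flank_window = NULL,
                            keep_intact_overlap = TRUE) {
  ann <- intact_annotation
  fams <- unique(ann$family)
  refs <- lapply(fams, function(f) {
    r <- ann[ann$family == f, ][1L, ]
    ltr <- extract_part(scaffolds, r, r$ltr5_start, r$ltr5_end)
    internal <- extract_part(scaffolds, r, r$internal_start, r$internal_end)
    list(ltr = ltr, internal = internal)
  })
  names(refs) <- fams

  queries <- unlist(lapply(fams, function(f)
    c(refs[[f]]$ltr, revcomp(refs[[f]]$ltr))))
  strands <- rep(c("+", "-"), length(fams))
  qids <- rep(fams, each = 2L)
  hits <- multi_query_search(scaffolds, queries, strands, qids,
                             min_identity, min_length, word_size, xdrop = 20)

  # drop hits overlapping an annotated intact element
  if (nrow(hits)) {
    bad <- logical(nrow(hits))
    for (sc in unique(hits$scaffold)) {
      a <- ann[ann$scaffold == sc, , drop = FALSE]
      if (!nrow(a)) next
      i <- which(hits$scaffold == sc)
      for (j in i)
        bad[j] <- any(hits$start[j] < a$end & hits$end[j] > a$start)
    }
    hits <- hits[!bad, , drop = FALSE]
  }
  # overlapping hits from different families/strands: best identity wins
  hits <- merge_hits(hits, by_strand = FALSE)

  intact_loci <- data.frame(
    element_id = ann$element_id, scaffold = ann$scaffold, start = ann$start,
    end = ann$end, strand = ann$strand, family = ann$family,
    superfamily = ann$superfamily, status = "intact",
    stringsAsFactors = FALSE)

  if (!nrow(hits)) return(intact_loci)
  sf_of <- setNames(ann$superfamily[!duplicated(ann$family)],
                    ann$family[!duplicated(ann$family)])
  status <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    fam <- hits$query_id[i]
    status[i] <- classify_locus(
      hits[i, ], refs[[fam]]$internal, scaffolds,
      flank_window = flank_window, min_identity = min_identity,
      min_length = min_length, word_size = word_size)
  }
  called <- data.frame(
    element_id = sprintf("locus_%04d", seq_len(nrow(hits))),
    scaffold = hits$scaffold, start = hits$start, end = hits$end,
    strand = hits$strand, family = hits$query_id,
    superfamily = unname(sf_of[hits$query_id]), status = status,
    stringsAsFactors = FALSE)
  if (!keep_intact_overlap)
    called <- called[called$status != "intact-overlap", , drop = FALSE]
  out <- rbind(intact_loci, called)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# strand-aware sequence extraction, 0-based half-open coordinates
extract_part <- function(scaffolds, row, s, e) {
  x <- substr(scaffolds[[row$scaffold]], s + 1L, e)
  if (row$strand == "-") revcomp(x) else x
}
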