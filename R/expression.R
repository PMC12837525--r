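# Assignment of genes to species-specific (SPE) vs syntenic (SYN) regions
# and two-group expression contrasts per developmental stage.

#' Assign genes to SPE or SYN regions
#'
#' Computes, per gene, the overlap in bases with SPE and with SYN regions.
#' The gene is assigned to the class holding more than half of its total
#' SPE+SYN overlap; genes overlapping both classes with neither reaching
#' the majority are "ambiguous", and genes overlapping neither are "none"
#' (both are excluded from downstream contrasts).
#'
#' @param genes data.frame: gene_id, scaffold, start, end.
#' @param regions region set with classes including SPE and SYN (normalized
#'   on entry).
#' @return data.frame: gene_id, class in {SPE, SYN, ambiguous, none},
#'   spe_overlap_bp, syn_overlap_bp.
#' @export
assign_region_class <- function(genes, regions) {
  check_intervals(genes, "genes")
  regions <- normalize_regions(regions)
  ov <- function(cl) {
    reg <- regions[regions$class == cl, , drop = FALSE]
    bp <- numeric(nrow(genes))
    for (sc in unique(genes$scaffold)) {
      gi <- which(genes$scaffold == sc)
      r <- reg[reg$scaffold == sc, , drop = FALSE]
      if (!nrow(r)) next
      gr <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
      rr <- IRanges::IRanges(r$start + 1L, r$end)
      hits <- IRanges::findOverlaps(gr, rr)
      if (length(hits)) {
        qi <- S4Vectors::queryHits(hits)
        w <- IRanges::width(IRanges::pintersect(gr[qi],
                                                rr[S4Vectors::subjectHits(hits)]))
        bp[gi] <- bp[gi] + as.numeric(tapply(w, factor(qi, seq_along(gi)),
                                             sum, default = 0))
      }
    }
    bp
  }
  spe <- ov("SPE")
  syn <- ov("SYN")
  tot <- spe + syn
  cls <- ifelse(tot == 0, "none",
         ifelse(spe / tot > 0.5, "SPE",
         ifelse(syn / tot > 0.5, "SYN", "ambiguous")))
  data.frame(gene_id = genes$gene_id, class = cls, spe_overlap_bp = spe,
             syn_overlap_bp = syn, stringsAsFactors = FALSE)
}

#' Two-group expression contrast for one stage
#'
#' Compares log2(x+1)-transformed expression of SPE-assigned vs
#' SYN-assigned genes at one developmental stage with a two-sided
#' two-sample t test (Welch by default; set `test = "student"` for the
#' pooled-variance variant). Optionally restricted to a gene set.
#'
#' @param expr expression data.frame: gene_id then one numeric column per
#'   stage.
#' @param assignment output of [assign_region_class()] (or any data.frame
#'   with gene_id and class).
#' @param stage stage column name (or index into the stage columns).
#' @param gene_set optional character vector of gene ids; NULL = all genes.
#' @param gene_set_label label recorded in the result.
#' @param test "welch" or "student".
#' @param transform "log2p1" or "none".
#' @return one-row data.frame of class `expression_contrast`: stage,
#'   gene_set, n_SPE, n_SYN, t, p, mean_diff (SPE - SYN on the transformed
#'   scale), significance.
#' @export
contrast <- function(expr, assignment, stage, gene_set = NULL,
                     gene_set_label = if (is.null(gene_set)) "all" else "set",
                     test = c("welch", "student"),
                     transform = c("log2p1", "none")) {
  test <- match.arg(test)
  transform <- match.arg(transform)
  stage_cols <- setdiff(names(expr), "gene_id")
  if (is.numeric(stage)) stage <- stage_cols[stage]
  if (!stage %in% stage_cols) stop_input("unknown stage '%s'", stage)
  ids <- expr$gene_id
  if (!is.null(gene_set)) ids <- intersect(ids, gene_set)
  cls <- assignment$class[match(ids, assignment$gene_id)]
  x <- expr[[stage]][match(ids, expr$gene_id)]
  if (any(x < 0, na.rm = TRUE)) stop_input("expression must be non-negative")
  if (transform == "log2p1") x <- log2(x + 1)
  a <- x[!is.na(cls) & cls == "SPE"]
  b <- x[!is.na(cls) & cls == "SYN"]
  if (length(a) < 2 || length(b) < 2)
    stop_input("need >= 2 genes per group at stage %s / set %s (SPE=%d, SYN=%d)",
               stage, gene_set_label, length(a), length(b))
  if (isTRUE(all.equal(var(a), 0)) && isTRUE(all.equal(var(b), 0)) &&
      isTRUE(all.equal(mean(a), mean(b)))) {
    tt <- list(statistic = c(t = 0), p.value = 1)   # degenerate identical groups
  } else {
    tt <- t.test(a, b, var.equal = (test == "student"))
  }
  res <- data.frame(stage = stage, gene_set = gene_set_label,
                    n_SPE = length(a), n_SYN = length(b),
                    t = unname(tt$statistic), p = tt$p.value,
                    mean_diff = mean(a) - mean(b),
                    significance = sig_tier(tt$p.value),
                    stringsAsFactors = FALSE)
  class(res) <- c("expression_contrast", class(res))
  res
}

sig_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Expression contrasts across all stages and gene sets
#'
#' @param expr expression matrix as in [contrast()].
#' @param assignment region assignment as in [contrast()].
#' @param gene_sets optional named list of gene-id vectors (e.g. pigment
#'   pathways); the unrestricted contrast is always included as "all".
#' @param ... passed to [contrast()].
#' @return data.frame with one row per stage x gene set.
#' @export
contrast_all <- function(expr, assignment, gene_sets = NULL, ...) {
  stages <- setdiff(names(expr), "gene_id")
  sets <- c(list(all = NULL), gene_sets)
  rows <- list()
  for (s in stages)
    for (g in names(sets))
      rows[[length(rows) + 1L]] <-
        contrast(expr, assignment, s, gene_set = sets[[g]],
                 gene_set_label = g, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
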