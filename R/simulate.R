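# Synthetic genome bundles with planted LTR-RT truth. Every downstream stage
# (census, dating, enrichment, duplication/pseudogene rules, expression
# contrast) is validated against the truth tables emitted here.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_genome()] and the
#' companion gene/expression simulators. Defaults describe a compact diploid-
#' like test genome of roughly 2 Mb carrying 50 intact, 100 solo and 30
#' truncated LTR-RT insertions across 6 families, with LTR-pair divergence
#' drawn up to P = 0.05 transitions and Q = 0.02 transversions per site --
#' young enough that flanking-homology classification should recover nearly
#' every planted element.
#'
#' @param n_scaffolds number of scaffolds; extra scaffolds are drawn when an
#'   unlucky length draw cannot hold the requested element load with its
#'   spacing.
#' @param scaffold_length_law list with `min`, `max` (bp) and power-law
#'   `shape`; lengths are drawn from a truncated Pareto so that many short
#'   scaffolds exist and the census stability scan has work to do.
#' @param n_intact,n_solo,n_truncated total planted element counts,
#'   distributed round-robin over families.
#' @param n_families number of LTR-RT families (alternating Gypsy/Copia).
#' @param ltr_length,internal_length,tsd_length element part lengths in bp.
#'   The 5 bp target-site duplication is planted identically on both flanks.
#' @param divergence_targets optional data.frame with columns `P`, `Q`
#'   (one row per intact element); `NULL` draws P ~ U(0, max_P) and
#'   Q ~ U(0, max_Q).
#' @param max_P,max_Q upper bounds for drawn divergence targets.
#' @param region_fractions named numeric, fraction of each scaffold assigned
#'   to structural-variation classes (INV/SPE/SYN); must sum to <= 1, the
#'   remainder is unlabeled.
#' @param ltr_placement_bias named relative placement weights per region
#'   class (classes absent default to 1); weight w means planted elements
#'   land in that class with probability proportional to w x class bases.
#' @param min_gap minimum distance in bp between planted elements, kept
#'   larger than the default classification flank window so a solo LTR never
#'   sees a neighbour's internal domain.
#' @param gene_count,td_clusters,pd_clusters,pseudogene_count gene-set
#'   simulator sizes (see [simulate_gene_set()]).
#' @param expression_effect mean log2-expression offset added to genes in
#'   SPE regions (see [simulate_expression()]).
#' @param stages number of developmental stages in the expression matrix.
#' @param seed integer seed; a fixed seed makes the whole bundle
#'   byte-identical across runs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 24,
                       scaffold_length_law = list(min = 3e4, max = 3e5, shape = 1.8),
                       n_intact = 50, n_solo = 100, n_truncated = 30,
                       n_families = 6,
                       ltr_length = 400, internal_length = 3000,
                       tsd_length = 5,
                       divergence_targets = NULL,
                       max_P = 0.05, max_Q = 0.02,
                       region_fractions = c(INV = 0.1, SPE = 0.3, SYN = 0.4),
                       ltr_placement_bias = c(INV = 1, SPE = 1, SYN = 1, none = 1),
                       min_gap = 5000,
                       gene_count = 200, td_clusters = 4, pd_clusters = 4,
                       pseudogene_count = 20,
                       expression_effect = -1, stages = 5,
                       seed = 1L) {
  cfg <- list(
    n_scaffolds = n_scaffolds, scaffold_length_law = scaffold_length_law,
    n_intact = n_intact, n_solo = n_solo, n_truncated = n_truncated,
    n_families = n_families, ltr_length = ltr_length,
    internal_length = internal_length, tsd_length = tsd_length,
    divergence_targets = divergence_targets, max_P = max_P, max_Q = max_Q,
    region_fractions = region_fractions,
    ltr_placement_bias = ltr_placement_bias, min_gap = min_gap,
    gene_count = gene_count, td_clusters = td_clusters,
    pd_clusters = pd_clusters, pseudogene_count = pseudogene_count,
    expression_effect = expression_effect, stages = stages,
    seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  cnt <- c("n_scaffolds", "n_intact", "n_solo", "n_truncated", "n_families",
           "ltr_length", "internal_length", "tsd_length", "gene_count",
           "td_clusters", "pd_clusters", "pseudogene_count", "stages")
  for (f in cnt)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop_input("config field %s must be a single non-negative number", f)
  if (cfg$stages < 1) stop_input("stages must be >= 1")
  fr <- cfg$region_fractions
  if (any(fr < 0 | fr > 1)) stop_input("region fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-9)
    stop_input("region fractions sum to %.3f > 1", sum(fr))
  law <- cfg$scaffold_length_law
  if (!all(c("min", "max", "shape") %in% names(law)) || law$min <= 0 ||
      law$max < law$min)
    stop_input("scaffold_length_law needs min <= max (both > 0) and shape")
  if (!is.null(cfg$divergence_targets)) {
    dt <- cfg$divergence_targets
    if (!all(c("P", "Q") %in% names(dt)) || nrow(dt) != cfg$n_intact)
      stop_input("divergence_targets must have P, Q columns and one row per intact element")
    if (any(dt$P + dt$Q > 0.75))
      stop_input("divergence targets must satisfy P + Q <= 0.75")
  }
  structure(cfg, class = "sim_config")
}

#' Plant substitutions at exact transition/transversion proportions
#'
#' Mutates a nucleotide sequence so that exactly `round(P * length)` sites
#' carry a transition and `round(Q * length)` distinct sites carry a
#' transversion relative to the input. Because every mutated site is sampled
#' without replacement (no multiple hits), the planted proportions are exactly
#' recoverable from a gap-free comparison of the two sequences, which makes
#' divergence dating an exact round-trip on simulated data.
#'
#' @param seq nucleotide string over ACGT.
#' @param P_target,Q_target transition / transversion site fractions;
#'   `P_target + Q_target` must be <= 0.75 and feasible for the length.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return mutated string of the same length.
#' @export
mutate_sequence <- function(seq, P_target, Q_target, seed = NULL) {
  seq <- check_dna(seq, "seq")
  n <- nchar(seq)
  if (P_target < 0 || Q_target < 0 || P_target + Q_target > 0.75)
    stop_input("require 0 <= P, Q and P + Q <= 0.75 (got P=%g, Q=%g)",
               P_target, Q_target)
  nP <- round(P_target * n)
  nQ <- round(Q_target * n)
  if (nP + nQ > n)
    stop_input("targets infeasible: %d transition + %d transversion sites for length %d",
               nP, nQ, n)
  with_seed(seed, {
    bases <- strsplit(seq, "")[[1]]
    sites <- sample.int(n, nP + nQ)
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    if (nP > 0) {
      i <- sites[seq_len(nP)]
      bases[i] <- transition[bases[i]]
    }
    if (nQ > 0) {
      i <- sites[nP + seq_len(nQ)]
      tv <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
      bases[i] <- vapply(bases[i], function(b) sample(tv[[b]], 1L), "")
    }
    paste(bases, collapse = "")
  })
}

draw_scaffold_lengths <- function(cfg) {
  law <- cfg$scaffold_length_law
  a <- law$shape
  u <- runif(cfg$n_scaffolds)
  if (abs(a - 1) < 1e-9) {
    len <- law$min * (law$max / law$min)^u
  } else {
    b <- 1 - a
    len <- (law$min^b + u * (law$max^b - law$min^b))^(1 / b)
  }
  as.integer(round(len))
}

# Partition each scaffold into labeled blocks whose per-class base totals
# match the configured fractions exactly (up to 1 bp rounding). Blocks of a
# class are cut into random-sized pieces and shuffled with the unlabeled
# remainder so classes interleave along the scaffold.
simulate_regions_impl <- function(scaffold_lengths, fractions,
                                  piece_mean = 2e4) {
  out <- list()
  for (sc in names(scaffold_lengths)) {
    L <- scaffold_lengths[[sc]]
    quota <- as.integer(floor(fractions * L))
    names(quota) <- names(fractions)
    quota <- c(quota, none = as.integer(L - sum(quota)))
    pieces_cls <- character(0)
    pieces_len <- integer(0)
    for (cl in names(quota)) {
      rem <- quota[[cl]]
      while (rem > 0) {
        take <- as.integer(min(rem, max(1000L, round(runif(1, 0.5, 1.5) * piece_mean))))
        pieces_cls <- c(pieces_cls, cl)
        pieces_len <- c(pieces_len, take)
        rem <- rem - take
      }
    }
    ord <- sample.int(length(pieces_len))
    pieces_cls <- pieces_cls[ord]
    pieces_len <- pieces_len[ord]
    ends <- cumsum(pieces_len)
    starts <- c(0L, ends[-length(ends)])
    keep <- pieces_cls != "none"
    if (any(keep))
      out[[sc]] <- data.frame(scaffold = sc, start = starts[keep],
                              end = ends[keep], class = pieces_cls[keep],
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate labeled structural-variation regions
#'
#' Lays non-overlapping INV/SPE/SYN blocks along each scaffold so that the
#' realized per-class base fractions match `region_fractions` to within
#' rounding. Unlabeled gaps make up the remainder.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @param config a [sim_config()] (only `region_fractions` and `seed` used),
#'   or a named fraction vector.
#' @param seed optional seed overriding the config seed.
#' @return data.frame with columns scaffold, start, end (0-based half-open),
#'   class.
#' @export
simulate_regions <- function(scaffold_lengths, config, seed = NULL) {
  fr <- if (inherits(config, "sim_config")) config$region_fractions else config
  if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-9)
    stop_input("region fractions must lie in [0,1] and sum to <= 1 (sum=%.3f)",
               sum(fr))
  seed <- seed %||% (if (inherits(config, "sim_config")) config$seed else NULL)
  with_seed(seed, simulate_regions_impl(scaffold_lengths, fr))
}

# weighted choice of an insertion point honoring region bias and min_gap
# subtract sorted forbidden intervals from [lo, hi]; returns matrix of
# remaining [start, end] (inclusive) segments of valid start positions
subtract_segments <- function(lo, hi, forb) {
  segs <- list()
  cur <- lo
  if (nrow(forb)) {
    forb <- forb[order(forb[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(forb))) {
      if (forb[k, 1] > cur) segs[[length(segs) + 1L]] <- c(cur, min(hi, forb[k, 1] - 1))
      cur <- max(cur, forb[k, 2] + 1)
      if (cur > hi) break
    }
  }
  if (cur <= hi) segs[[length(segs) + 1L]] <- c(cur, hi)
  if (!length(segs)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, segs)
}

# choose an insertion start honoring region bias and min_gap. A piece is
# drawn with probability proportional to bias weight x length, then the
# start is drawn uniformly over the positions actually free in that piece;
# exhausted pieces are retired so placement only fails when no free
# position exists anywhere.
place_element <- function(len, scaffolds_len, region_pieces, bias, occupied,
                          min_gap) {
  w <- region_pieces$weight *
    pmax(0, region_pieces$end - region_pieces$start)
  repeat {
    if (all(w <= 0))
      stop_input("no room left to place a %d bp element: genome too crowded",
                 len)
    pi <- sample.int(nrow(region_pieces), 1L, prob = w)
    p <- region_pieces[pi, ]
    sc <- p$scaffold
    lo <- p$start
    hi <- min(p$end - 1L, scaffolds_len[[sc]] - len)
    if (hi < lo) { w[pi] <- 0; next }
    occ <- occupied[[sc]]
    forb <- if (!is.null(occ) && nrow(occ))
      cbind(occ$start - len - min_gap + 1, occ$end + min_gap - 1)
    else matrix(numeric(0), ncol = 2)
    segs <- subtract_segments(lo, hi, forb)
    if (!nrow(segs)) { w[pi] <- 0; next }
    seg_len <- segs[, 2] - segs[, 1] + 1
    off <- sample.int(sum(seg_len), 1L)
    cum <- cumsum(seg_len)
    si <- which(off <= cum)[1]
    start <- as.integer(segs[si, 1] + (off - 1) - c(0, cum)[si])
    return(list(scaffold = sc, start = start))
  }
}

#' Simulate a genome bundle with planted LTR-RT truth
#'
#' Generates random scaffolds, labels structural-variation regions, and
#' plants intact (TSD + 5' LTR + internal + 3' LTR + TSD), solo
#' (TSD + LTR + TSD) and truncated (LTR plus a partial internal fragment on
#' one side only) LTR-RT copies at non-overlapping positions, optionally
#' biased toward chosen region classes. The 3' LTR of each intact element is
#' the 5' LTR mutated to a planted (P, Q) divergence via [mutate_sequence()],
#' so insertion dating has an exact ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `ltr_bundle` with components `scaffolds` (named
#'   character vector), `truth` (element truth table, 0-based half-open
#'   coordinates), `intact_annotation` (classification input: per intact
#'   element the LTR5/internal/LTR3 intervals), `regions`, `refs` (per-family
#'   LTR and internal reference sequences), `scaffold_lengths`, `config`.
#' @export
simulate_genome <- function(config) {
  cfg <- validate_sim_config(config)
  with_seed(cfg$seed, {
    slen <- draw_scaffold_lengths(cfg)
    names(slen) <- sprintf("scaf%02d", seq_along(slen))
    total <- sum(slen)
    footprint <- cfg$n_intact * (2 * cfg$ltr_length + cfg$internal_length +
                                   2 * cfg$tsd_length) +
      cfg$n_solo * (cfg$ltr_length + 2 * cfg$tsd_length) +
      cfg$n_truncated * (cfg$ltr_length + ceiling(cfg$internal_length / 2))
    n_elem <- cfg$n_intact + cfg$n_solo + cfg$n_truncated
    # top up with extra scaffolds (up to 10x the requested number) when an
    # unlucky length draw leaves no room for the requested element load
    budget <- 1.2 * (footprint + n_elem * cfg$min_gap)
    while (total < budget && length(slen) < 10 * cfg$n_scaffolds) {
      extra <- draw_scaffold_lengths(cfg)[1L]
      slen <- c(slen, extra)
      total <- total + extra
    }
    names(slen) <- sprintf("scaf%02d", seq_along(slen))
    if (footprint + n_elem * cfg$min_gap > total)
      stop_input("requested elements (%d bp + gaps) exceed total scaffold length (%d bp)",
                 footprint, total)
    scaffolds <- vapply(slen, rand_dna, "")

    regions <- simulate_regions_impl(slen, cfg$region_fractions)
    # piece table including unlabeled gaps, with bias weights
    pieces <- rbind(regions,
                    unlabeled_gaps(regions, slen))
    bias <- cfg$ltr_placement_bias
    pieces$weight <- ifelse(pieces$class %in% names(bias),
                            bias[pieces$class], 1)

    fam <- sprintf("F%02d", seq_len(cfg$n_families))
    superfam <- rep(c("Gypsy", "Copia"), length.out = cfg$n_families)
    refs <- lapply(fam, function(f) list(
      ltr = rand_dna(cfg$ltr_length),
      internal = rand_dna(cfg$internal_length)))
    names(refs) <- fam

    dt <- cfg$divergence_targets
    if (is.null(dt) && cfg$n_intact > 0)
      dt <- data.frame(P = runif(cfg$n_intact, 0, cfg$max_P),
                       Q = runif(cfg$n_intact, 0, cfg$max_Q))

    statuses <- c(rep("intact", cfg$n_intact), rep("solo", cfg$n_solo),
                  rep("truncated", cfg$n_truncated))
    fam_of <- rep(fam, length.out = length(statuses))
    occupied <- setNames(vector("list", length(slen)), names(slen))
    truth <- vector("list", length(statuses))
    annot <- list()
    ii <- 0L
    for (e in seq_along(statuses)) {
      st <- statuses[e]
      f <- fam_of[e]
      strand <- sample(c("+", "-"), 1L)
      ltr <- refs[[f]]$ltr
      if (st == "intact") {
        ii <- ii + 1L
        P <- dt$P[ii]; Q <- dt$Q[ii]
        ltr3 <- mutate_sequence(ltr, P, Q)
        cass_parts <- c(ltr, refs[[f]]$internal, ltr3)
      } else if (st == "solo") {
        P <- runif(1, 0, cfg$max_P); Q <- runif(1, 0, cfg$max_Q)
        cass_parts <- mutate_sequence(ltr, P, Q)
      } else {
        P <- runif(1, 0, cfg$max_P); Q <- runif(1, 0, cfg$max_Q)
        frag <- substr(refs[[f]]$internal, 1L, ceiling(cfg$internal_length / 2))
        cass_parts <- c(mutate_sequence(ltr, P, Q), frag)
      }
      tsd <- rand_dna(cfg$tsd_length)
      cassette <- paste0(tsd, paste(cass_parts, collapse = ""), tsd)
      if (strand == "-") cassette <- paste0(
        tsd, revcomp(paste(cass_parts, collapse = "")), tsd)
      len <- nchar(cassette)
      pos <- place_element(len, slen, pieces, bias, occupied, cfg$min_gap)
      sc <- pos$scaffold
      substr(scaffolds[[sc]], pos$start + 1L, pos$start + len) <- cassette
      occupied[[sc]] <- rbind(occupied[[sc]],
                              data.frame(start = pos$start, end = pos$start + len))
      el_start <- as.integer(pos$start + cfg$tsd_length)   # element without TSDs
      el_end <- as.integer(pos$start + len - cfg$tsd_length)
      id <- sprintf("%s_%03d", st, e)
      truth[[e]] <- data.frame(
        element_id = id, scaffold = sc, start = el_start, end = el_end,
        strand = strand, status = st, family = f,
        superfamily = superfam[match(f, fam)],
        P = P, Q = Q, stringsAsFactors = FALSE)
      if (st == "intact") {
        L <- cfg$ltr_length; IL <- cfg$internal_length
        if (strand == "+") {
          iv <- list(ltr5 = c(el_start, el_start + L),
                     internal = c(el_start + L, el_start + L + IL),
                     ltr3 = c(el_end - L, el_end))
        } else {
          iv <- list(ltr5 = c(el_end - L, el_end),
                     internal = c(el_start + L, el_start + L + IL),
                     ltr3 = c(el_start, el_start + L))
        }
        iv <- lapply(iv, as.integer)
        annot[[length(annot) + 1L]] <- data.frame(
          element_id = id, scaffold = sc, start = el_start, end = el_end,
          strand = strand, family = f, superfamily = superfam[match(f, fam)],
          ltr5_start = iv$ltr5[1], ltr5_end = iv$ltr5[2],
          internal_start = iv$internal[1], internal_end = iv$internal[2],
          ltr3_start = iv$ltr3[1], ltr3_end = iv$ltr3[2],
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth) %||%
      data.frame(element_id = character(0))
    annot <- if (length(annot)) do.call(rbind, annot) else NULL
    structure(list(
      scaffolds = scaffolds, scaffold_lengths = slen, truth = truth,
      intact_annotation = annot, regions = regions, refs = refs,
      config = cfg), class = "ltr_bundle")
  })
}

unlabeled_gaps <- function(regions, scaffold_lengths) {
  out <- list()
  for (sc in names(scaffold_lengths)) {
    r <- regions[regions$scaffold == sc, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(r$start, r$end)), scaffold_lengths[[sc]])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (any(keep))
      out[[sc]] <- data.frame(scaffold = sc, start = starts[keep],
                              end = ends[keep], class = "none",
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.ltr_bundle <- function(x, ...) {
  cat(sprintf("ltr_bundle: %d scaffolds, %s bp total\n",
              length(x$scaffolds),
              format(sum(x$scaffold_lengths), big.mark = ",")))
  cat("planted elements:\n")
  print(table(x$truth$status))
  invisible(x)
}

#' Simulate a gene set with planted duplication and pseudogene truth
#'
#' Lays `gene_count` genes along a dedicated gene scaffold, plants tandem
#' (adjacent) and proximal (1-10 intervening genes) homolog pairs plus
#' distant control pairs, assigns genes to SPE/SYN expression regions, and
#' emits pseudogene candidates whose identity/coverage values straddle the
#' filtering thresholds (30% identity, 50% parent coverage), including the
#' exact boundary cases.
#'
#' @param config a [sim_config()].
#' @param seed optional override of the config seed.
#' @return list with `genes` (gene_id, scaffold, start, end, strand,
#'   region_class), `pairs` (gene_a, gene_b, true_type, intervening),
#'   `pseudogenes` (pseudo_id, parent_id, identity, coverage, true_kept),
#'   `regions` (SPE/SYN blocks on the gene scaffold).
#' @export
simulate_gene_set <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  with_seed(seed %||% cfg$seed, {
    n <- cfg$gene_count
    glen <- 2000L; gap <- 1000L
    starts <- (seq_len(n) - 1L) * (glen + gap) + 500L
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)), scaffold = "chrG1",
      start = starts, end = starts + glen,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    scaf_len <- max(genes$end) + 500L

    # SPE/SYN blocks aligned to gene boundaries; every 10th gene unassigned
    cls <- rep(c("SPE", "SYN"), length.out = n)
    cls[seq(10L, n, by = 10L)] <- "none"
    genes$region_class <- cls
    reg <- genes[genes$region_class != "none",
                 c("scaffold", "start", "end", "region_class")]
    reg$start <- reg$start - 100L
    reg$end <- reg$end + 100L
    names(reg)[4] <- "class"
    rownames(reg) <- NULL

    # homolog pairs: TD (adjacent), PD (1..10 intervening, always including
    # the 10-gene boundary), and distant controls (>10, always including 11)
    used <- logical(n)
    pick_pair <- function(gap_genes) {
      for (i in seq_len(1000L)) {
        a <- sample.int(n - gap_genes - 1L, 1L)
        b <- a + gap_genes + 1L
        if (!used[a] && !used[b]) {
          used[c(a, b)] <<- TRUE
          return(c(a, b))
        }
      }
      stop_input("could not place homolog pairs: gene set too small")
    }
    pairs <- list()
    add_pair <- function(idx, type, gap_genes) {
      pairs[[length(pairs) + 1L]] <<- data.frame(
        gene_a = genes$gene_id[idx[1]], gene_b = genes$gene_id[idx[2]],
        true_type = type, intervening = gap_genes, stringsAsFactors = FALSE)
    }
    for (i in seq_len(cfg$td_clusters)) add_pair(pick_pair(0L), "TD", 0L)
    pd_gaps <- c(10L, sample(1:10, max(0L, cfg$pd_clusters - 1L), replace = TRUE))
    pd_gaps <- pd_gaps[seq_len(cfg$pd_clusters)]
    for (g in pd_gaps) add_pair(pick_pair(g), "PD", g)
    none_gaps <- c(11L, sample(12:20, 2L, replace = TRUE))
    for (g in none_gaps) add_pair(pick_pair(g), "none", g)
    pairs <- do.call(rbind, pairs)

    # pseudogene candidates straddling the identity/coverage thresholds
    np <- max(cfg$pseudogene_count, 4L)
    identity <- runif(np, 5, 95)
    coverage <- runif(np, 10, 95)
    identity[1:4] <- c(30, 31, 80, 29)     # boundary and near-boundary cases
    coverage[1:4] <- c(90, 60, 50, 90)
    parents <- sample(genes$gene_id, np, replace = TRUE)
    pseudo <- data.frame(
      pseudo_id = sprintf("ps%03d", seq_len(np)), scaffold = "chrG1",
      start = sample.int(scaf_len - 600L, np), parent_id = parents,
      identity = identity, coverage = coverage, stringsAsFactors = FALSE)
    pseudo$end <- pseudo$start + 500L
    pseudo$true_kept <- pseudo$identity > 30 & pseudo$coverage > 50
    pseudo <- pseudo[, c("pseudo_id", "scaffold", "start", "end", "parent_id",
                         "identity", "coverage", "true_kept")]
    list(genes = genes, pairs = pairs, pseudogenes = pseudo, regions = reg)
  })
}

#' Simulate a stage-wise expression matrix
#'
#' Draws log-normal expression for each gene across developmental stages and
#' adds the configured offset, on the log2 scale, to genes whose
#' `region_class` is SPE. This emulates an expression difference between
#' species-specific and syntenic genomic context.
#'
#' @param genes data.frame with `gene_id` and `region_class` columns (as from
#'   [simulate_gene_set()]).
#' @param effect mean log2 offset applied to SPE-resident genes.
#' @param stages number of stage columns.
#' @param seed optional integer seed.
#' @param base_log2_mean,log2_sd location and spread of the baseline
#'   log2-expression distribution.
#' @return data.frame: gene_id then one numeric column per stage.
#' @export
simulate_expression <- function(genes, effect = -1, stages = 5, seed = NULL,
                                base_log2_mean = 5, log2_sd = 1) {
  if (stages < 1) stop_input("stages must be >= 1")
  with_seed(seed, {
    n <- nrow(genes)
    offset <- ifelse(genes$region_class == "SPE", effect, 0)
    m <- matrix(2^(rnorm(n * stages, base_log2_mean, log2_sd) + offset),
                nrow = n)
    out <- data.frame(gene_id = genes$gene_id, m, stringsAsFactors = FALSE)
    names(out) <- c("gene_id", sprintf("stage_%d", seq_len(stages)))
    out
  })
}
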