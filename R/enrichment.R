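# Overlap of LTR intervals with structural-variation region classes
# (INV / SPE / SYN) against a randomization null, plus the per-class
# coverage proportions of species-specific LTRs.

#' Normalize a region set
#'
#' Sorts regions and merges overlapping intervals within each class
#' (cross-class overlaps are left intact; each class is evaluated
#' independently).
#'
#' @param regions data.frame: scaffold, start, end (0-based half-open),
#'   class.
#' @return normalized data.frame of the same shape.
#' @export
normalize_regions <- function(regions) {
  check_intervals(regions, "regions")
  if (!"class" %in% names(regions))
    stop_input("regions must have a class column")
  out <- list()
  for (cl in unique(regions$class)) {
    r <- regions[regions$class == cl, , drop = FALSE]
    for (sc in unique(r$scaffold)) {
      x <- r[r$scaffold == sc, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = IRanges::start(ir) - 1L,
        end = IRanges::end(ir), class = cl, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$class, res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# fast overlap indicator against merged, sorted regions of one scaffold:
# [a, b) overlaps some region iff the last region starting at or before a is
# still open past a, or the next region starts before b
overlaps_any0 <- function(a, b, reg_start, reg_end) {
  if (!length(reg_start)) return(logical(length(a)))
  i <- findInterval(a, reg_start)
  hit1 <- i >= 1L & reg_end[pmax(i, 1L)] > a
  j <- i + 1L
  hit2 <- j <= length(reg_start) & reg_start[pmin(j, length(reg_start))] < b
  hit1 | hit2
}

#' Count intervals overlapping a region class
#'
#' Number of input intervals overlapping, by at least 1 bp, any region of
#' the given class. Coordinates are 0-based half-open, so an interval
#' abutting a region (end == region start) does not overlap it.
#'
#' @param intervals data.frame: scaffold, start, end.
#' @param regions normalized region set (see [normalize_regions()]).
#' @param class region class to count against.
#' @return integer count.
#' @export
overlap_count <- function(intervals, regions, class) {
  check_intervals(intervals, "intervals")
  if (!class %in% regions$class)
    stop_input("unknown region class '%s'", class)
  reg <- regions[regions$class == class, , drop = FALSE]
  n <- 0L
  for (sc in unique(intervals$scaffold)) {
    iv <- intervals[intervals$scaffold == sc, , drop = FALSE]
    r <- reg[reg$scaffold == sc, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    n <- n + sum(overlaps_any0(iv$start, iv$end, r$start, r$end))
  }
  n
}

#' Randomly re-place intervals across scaffolds
#'
#' Draws, for each input interval, a new location of identical length:
#' the scaffold is chosen with probability proportional to its length among
#' scaffolds long enough to hold the interval, and the start uniformly over
#' valid positions. The output length multiset equals the input's; random
#' intervals may overlap each other.
#'
#' @param intervals data.frame: scaffold, start, end.
#' @param scaffold_lengths named scaffold length vector.
#' @param seed optional integer seed.
#' @return data.frame of randomized intervals.
#' @export
randomize_intervals <- function(intervals, scaffold_lengths, seed = NULL) {
  check_intervals(intervals, "intervals")
  len <- intervals$end - intervals$start
  if (length(len) && max(len) > max(scaffold_lengths))
    stop_input("an interval of %d bp is longer than every scaffold", max(len))
  with_seed(seed, {
    scn <- names(scaffold_lengths)
    n <- length(len)
    if (n && max(len) <= min(scaffold_lengths)) {
      # every interval fits everywhere: fully vectorized draw
      pick <- sample.int(length(scaffold_lengths), n, replace = TRUE,
                         prob = scaffold_lengths)
      start <- floor(runif(n) * (scaffold_lengths[pick] - len + 1))
      sc <- scn[pick]
    } else {
      sc <- character(n)
      start <- numeric(n)
      for (i in seq_len(n)) {
        ok <- which(scaffold_lengths >= len[i])
        pick <- ok[sample.int(length(ok), 1L, prob = scaffold_lengths[ok])]
        sc[i] <- scn[pick]
        start[i] <- sample.int(scaffold_lengths[pick] - len[i] + 1L, 1L) - 1L
      }
    }
    data.frame(scaffold = sc, start = as.integer(start),
               end = as.integer(start + len), stringsAsFactors = FALSE)
  })
}

#' Permutation test of LTR overlap with a region class
#'
#' Compares the observed number of intervals overlapping a region class with
#' a null distribution obtained by re-placing the intervals at random
#' (length-preserving) `n_perm` times. Empirical p-values use the +1
#' correction \eqn{p = (1 + \#\{null \ge obs\}) / (n_{perm} + 1)} (and
#' \eqn{\le} for depletion), so p is never exactly 0.
#'
#' @param intervals data.frame: scaffold, start, end.
#' @param regions region set (normalized on entry).
#' @param class region class tested.
#' @param scaffold_lengths named scaffold length vector.
#' @param n_perm number of randomizations (>= 99).
#' @param seed integer seed for the null.
#' @return object of class `overlap_test`: observed, null_mean, null_sd,
#'   z_score (NA when the null is degenerate), p_enrich, p_deplete, n_perm,
#'   seed, null_samples.
#' @export
permutation_enrichment <- function(intervals, regions, class,
                                   scaffold_lengths, n_perm = 1000,
                                   seed = 1L) {
  if (n_perm < 99) stop_input("n_perm must be >= 99")
  regions <- normalize_regions(regions)
  reg <- regions[regions$class == class, , drop = FALSE]
  if (!nrow(reg)) stop_input("unknown region class '%s'", class)
  # pre-sort per scaffold once
  reg_by_sc <- split(reg, reg$scaffold)
  reg_by_sc <- lapply(reg_by_sc, function(r) r[order(r$start), , drop = FALSE])
  count_fast <- function(iv) {
    n <- 0L
    for (sc in unique(iv$scaffold)) {
      r <- reg_by_sc[[sc]]
      sub <- iv$scaffold == sc
      if (is.null(r)) next
      n <- n + sum(overlaps_any0(iv$start[sub], iv$end[sub], r$start, r$end))
    }
    n
  }
  observed <- count_fast(intervals)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      count_fast(randomize_intervals(intervals, scaffold_lengths))
    }, numeric(1))
  })
  mu <- mean(null); s <- sd(null)
  structure(list(
    class = class, observed = observed, null_mean = mu, null_sd = s,
    z_score = if (isTRUE(s > 0)) (observed - mu) / s else NA_real_,
    p_enrich = (1 + sum(null >= observed)) / (n_perm + 1),
    p_deplete = (1 + sum(null <= observed)) / (n_perm + 1),
    n_perm = n_perm, seed = seed, null_samples = null),
    class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap test vs %s: observed %d, null %.1f +/- %.1f (n_perm=%d)\n",
              x$class, x$observed, x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  z = %s, p_enrich = %.4g, p_deplete = %.4g\n",
              ifelse(is.na(x$z_score), "undef.", sprintf("%.2f", x$z_score)),
              x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Per-class coverage by species-specific LTR intervals
#'
#' For each region class, the percentage of its bases covered by at least
#' one LTR interval (coverage, not summed lengths: overlapping LTRs are
#' merged first). With a `superfamily` column on the intervals a per-
#' superfamily breakdown is added.
#'
#' @param regions region set (normalized on entry).
#' @param ltr_intervals data.frame: scaffold, start, end, optional
#'   superfamily.
#' @return data.frame: class, group ("all" or a superfamily), class_bp,
#'   covered_bp, percent (full precision; NA for a class with zero bases).
#' @export
class_coverage <- function(regions, ltr_intervals) {
  regions <- normalize_regions(regions)
  check_intervals(ltr_intervals, "ltr_intervals")
  groups <- list(all = ltr_intervals)
  if ("superfamily" %in% names(ltr_intervals))
    groups <- c(groups, split(ltr_intervals, ltr_intervals$superfamily))
  out <- list()
  for (cl in unique(regions$class)) {
    reg <- regions[regions$class == cl, , drop = FALSE]
    class_bp <- sum(reg$end - reg$start)
    for (g in names(groups)) {
      iv <- groups[[g]]
      cov <- 0L
      for (sc in unique(reg$scaffold)) {
        r <- reg[reg$scaffold == sc, , drop = FALSE]
        x <- iv[iv$scaffold == sc, , drop = FALSE]
        if (!nrow(x)) next
        ir_r <- IRanges::IRanges(r$start + 1L, r$end)
        ir_x <- IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
        cov <- cov + sum(IRanges::width(IRanges::intersect(ir_r, ir_x)))
      }
      out[[length(out) + 1L]] <- data.frame(
        class = cl, group = g, class_bp = class_bp, covered_bp = cov,
        percent = if (class_bp > 0) 100 * cov / class_bp else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
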