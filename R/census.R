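# Birth/death census of LTR-RT loci: solo:intact ratio statistics, the
# family-level high-elimination proportion, and the scaffold-length
# stabilization scan.

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

# family percentages are conventionally truncated (not rounded) to two
# decimals in published census tables; ratios use half-up rounding
trunc2 <- function(x) floor(x * 100) / 100

#' Build a census table from intact/solo/truncated counts
#'
#' Computes the birth/death ratio statistics S:I, T:I, (S+T):I and S+T+I
#' from element counts, optionally alongside counts recomputed after
#' scaffold-length filtering and a family-level summary (number of families,
#' number with S:I > 3, and their percentage). Ratios are kept at full
#' precision; the print method formats them to two decimals, rounding half
#' up. When I = 0 the ratios are undefined and reported as NA.
#'
#' @param I,S,T intact / solo / truncated element counts.
#' @param filtered_I,filtered_S,filtered_T counts after dropping loci on
#'   scaffolds shorter than `filtered_scaffold_length` (default: unfiltered).
#' @param filtered_scaffold_length the length threshold applied, bp.
#' @param n_families,n_high optional family summary: total number of
#'   families and number with S:I > 3.
#' @return object of class `ltr_census`.
#' @export
census_table <- function(I, S, T,
                         filtered_I = I, filtered_S = S, filtered_T = T,
                         filtered_scaffold_length = 0,
                         n_families = NA_integer_, n_high = NA_integer_) {
  for (v in list(I, S, T, filtered_I, filtered_S, filtered_T))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop_input("counts must be single non-negative numbers")
  if (filtered_I > I || filtered_S > S || filtered_T > T)
    stop_input("filtered counts cannot exceed unfiltered counts")
  structure(list(
    I = I, S = S, T = T, ST = S + T, STI = S + T + I,
    S_over_I = ratio_or_na(S, I),
    T_over_I = ratio_or_na(T, I),
    ST_over_I = ratio_or_na(S + T, I),
    filtered_scaffold_length = filtered_scaffold_length,
    filtered_I = filtered_I, filtered_S = filtered_S,
    filtered_T = filtered_T,
    filtered_S_over_I = ratio_or_na(filtered_S, filtered_I),
    filtered_T_over_I = ratio_or_na(filtered_T, filtered_I),
    filtered_ST_over_I = ratio_or_na(filtered_S + filtered_T, filtered_I),
    n_families = n_families, n_high = n_high,
    proportion_high = if (is.na(n_families) || n_families == 0) NA_real_
                      else 100 * n_high / n_families,
    proportion_high_2dp = if (is.na(n_families) || n_families == 0) NA_real_
                          else trunc2(100 * n_high / n_families)
  ), class = "ltr_census")
}

fmt2 <- function(x) ifelse(is.na(x), "undef.",
                           sprintf("%.2f", round_half_up(x, 2)))

#' @export
print.ltr_census <- function(x, ...) {
  cat("LTR-RT birth/death census\n")
  cat(sprintf("  I=%d  S=%d  T=%d  S+T=%d  S+T+I=%d\n",
              x$I, x$S, x$T, x$ST, x$STI))
  cat(sprintf("  S/I=%s  T/I=%s  (S+T)/I=%s\n",
              fmt2(x$S_over_I), fmt2(x$T_over_I), fmt2(x$ST_over_I)))
  cat(sprintf("  filtered (scaffolds >= %s bp): I=%d S=%d T=%d  S/I=%s T/I=%s (S+T)/I=%s\n",
              format(x$filtered_scaffold_length, big.mark = ","),
              x$filtered_I, x$filtered_S, x$filtered_T,
              fmt2(x$filtered_S_over_I), fmt2(x$filtered_T_over_I),
              fmt2(x$filtered_ST_over_I)))
  if (!is.na(x$n_families))
    cat(sprintf("  families: %d total, %d with S/I > 3 (%.2f%%)\n",
                x$n_families, x$n_high, x$proportion_high_2dp))
  invisible(x)
}

status_counts <- function(loci) {
  c(I = sum(loci$status == "intact"),
    S = sum(loci$status == "solo"),
    T = sum(loci$status == "truncated"))
}

#' Run the LTR-RT census over classified loci
#'
#' Counts intact, solo and truncated loci, excludes loci on scaffolds
#' shorter than `min_scaffold_length` for the filtered columns, and derives
#' the ratio statistics via [census_table()].
#'
#' @param loci data.frame with at least scaffold and status columns
#'   (statuses in intact/solo/truncated; other statuses are ignored with a
#'   warning).
#' @param scaffold_lengths named vector covering every scaffold referenced.
#' @param min_scaffold_length length threshold in bp for the filtered counts.
#' @return object of class `ltr_census`.
#' @export
run_census <- function(loci, scaffold_lengths, min_scaffold_length = 0) {
  known <- loci$status %in% c("intact", "solo", "truncated")
  if (any(!known)) {
    warning(sprintf("%d loci with status outside {intact, solo, truncated} ignored",
                    sum(!known)))
    loci <- loci[known, , drop = FALSE]
  }
  miss <- setdiff(unique(loci$scaffold), names(scaffold_lengths))
  if (length(miss))
    stop_input("scaffold_lengths missing scaffolds: %s",
               paste(head(miss, 3), collapse = ", "))
  cnt <- status_counts(loci)
  keep <- scaffold_lengths[loci$scaffold] >= min_scaffold_length
  fcnt <- status_counts(loci[keep, , drop = FALSE])
  census_table(I = cnt[["I"]], S = cnt[["S"]], T = cnt[["T"]],
               filtered_I = fcnt[["I"]], filtered_S = fcnt[["S"]],
               filtered_T = fcnt[["T"]],
               filtered_scaffold_length = min_scaffold_length)
}

#' Per-family census and high-elimination proportion
#'
#' Computes I, S, T and S:I per family and the proportion of families whose
#' S:I ratio exceeds 3, the summary used to compare LTR-RT elimination
#' ability between genomes. Families with I = 0 but S+T > 0 represent
#' complete elimination: their ratio is treated as +Inf (> 3) and they are
#' counted as high-elimination.
#'
#' @param loci classified loci with family and status columns.
#' @param threshold S:I ratio above which a family counts as
#'   high-elimination.
#' @return list of class `ltr_family_census`: `families` data.frame
#'   (family, I, S, T, S_over_I, high), `n_families`, `n_high`,
#'   `proportion_high` (percent, full precision).
#' @export
family_census <- function(loci, threshold = 3) {
  if (!nrow(loci))
    return(structure(list(families = data.frame(), n_families = 0L,
                          n_high = 0L, proportion_high = NA_real_,
                          proportion_high_2dp = NA_real_),
                     class = "ltr_family_census"))
  fams <- sort(unique(loci$family))
  rows <- lapply(fams, function(f) {
    cnt <- status_counts(loci[loci$family == f, , drop = FALSE])
    r <- if (cnt[["I"]] > 0) cnt[["S"]] / cnt[["I"]]
         else if (cnt[["S"]] + cnt[["T"]] > 0) Inf else NA_real_
    data.frame(family = f, I = cnt[["I"]], S = cnt[["S"]], T = cnt[["T"]],
               S_over_I = r, high = isTRUE(r > threshold),
               stringsAsFactors = FALSE)
  })
  fam_df <- do.call(rbind, rows)
  rownames(fam_df) <- NULL
  prop <- 100 * sum(fam_df$high) / nrow(fam_df)
  structure(list(families = fam_df, n_families = nrow(fam_df),
                 n_high = sum(fam_df$high),
                 proportion_high = prop,
                 proportion_high_2dp = trunc2(prop)),
            class = "ltr_family_census")
}

#' @export
print.ltr_family_census <- function(x, ...) {
  cat(sprintf("family census: %d families, %d with S/I > 3 (%s%%)\n",
              x$n_families, x$n_high,
              ifelse(is.na(x$proportion_high_2dp), "undef.",
                     sprintf("%.2f", x$proportion_high_2dp))))
  invisible(x)
}

#' Scaffold-length stabilization scan of the S:I ratio
#'
#' Short scaffolds inflate the solo count (intact elements rarely fit on
#' them), so the S:I ratio is recomputed over a grid of minimum scaffold
#' lengths until it stabilizes. The selected threshold is the first grid
#' point after which the relative change in S:I stays below `tolerance` for
#' `patience` consecutive grid steps; if the ratio never stabilizes the scan
#' selects 0 and flags itself unstable. If some threshold removes every
#' intact element the scan is truncated there with a warning flag.
#'
#' @param loci classified loci.
#' @param scaffold_lengths named scaffold length vector.
#' @param grid increasing vector of length thresholds starting at 0;
#'   default: 0 plus the deciles of the scaffold-length distribution.
#' @param tolerance maximum relative change in S:I regarded as stable.
#' @param patience number of consecutive stable steps required.
#' @return object of class `ltr_stability_scan`: data.frame `scan`
#'   (threshold, I, S, T, S_over_I, rel_change), `selected_threshold`,
#'   `stable`, `truncated`.
#' @export
stability_scan <- function(loci, scaffold_lengths, grid = NULL,
                           tolerance = 0.01, patience = 2) {
  if (tolerance <= 0) stop_input("tolerance must be > 0")
  if (is.null(grid)) {
    dec <- unname(quantile(scaffold_lengths, probs = seq(0.1, 0.9, 0.1),
                           type = 1))
    grid <- sort(unique(c(0, dec)))
  }
  if (is.unsorted(grid, strictly = TRUE) || grid[1] != 0)
    stop_input("grid must be strictly increasing and start at 0")
  n <- length(grid)
  I <- S <- T <- integer(n)
  truncated <- FALSE
  last <- n
  for (i in seq_len(n)) {
    keep <- scaffold_lengths[loci$scaffold] >= grid[i]
    cnt <- status_counts(loci[keep, , drop = FALSE])
    I[i] <- cnt[["I"]]; S[i] <- cnt[["S"]]; T[i] <- cnt[["T"]]
    if (I[i] == 0 && i > 1) {       # ratio undefined from here on
      truncated <- TRUE
      last <- i - 1L
      break
    }
    last <- i
  }
  idx <- seq_len(last)
  ratio <- ifelse(I[idx] > 0, S[idx] / I[idx], NA_real_)
  d <- abs(diff(ratio))
  prev <- ratio[-length(ratio)]
  rel <- c(NA_real_, ifelse(prev > 0, d / prev, ifelse(d == 0, 0, Inf)))
  scan <- data.frame(threshold = grid[idx], I = I[idx], S = S[idx],
                     T = T[idx], S_over_I = ratio, rel_change = rel)
  selected <- NA_real_
  stable <- FALSE
  if (last == 1L) {
    selected <- grid[1]
    stable <- TRUE
  } else {
    for (i in seq_len(last)) {
      js <- i + seq_len(patience)
      if (any(js > last)) break        # not enough grid left for full patience
      if (all(rel[js] < tolerance, na.rm = FALSE) && !anyNA(rel[js])) {
        selected <- grid[i]
        stable <- TRUE
        break
      }
    }
    if (!stable) selected <- 0
  }
  structure(list(scan = scan, selected_threshold = selected,
                 stable = stable, truncated = truncated,
                 tolerance = tolerance, patience = patience),
            class = "ltr_stability_scan")
}

#' @export
print.ltr_stability_scan <- function(x, ...) {
  cat(sprintf("S:I stability scan (%d thresholds)%s\n", nrow(x$scan),
              if (x$truncated) " [truncated: I reached 0]" else ""))
  print(x$scan, row.names = FALSE)
  cat(sprintf("selected threshold: %s bp (%s)\n",
              format(x$selected_threshold, big.mark = ","),
              if (x$stable) "stable" else "never stabilized"))
  invisible(x)
}
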