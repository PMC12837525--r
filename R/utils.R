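# Internal helpers shared across modules. All genomic intervals inside the
# package are 0-based half-open [start, end); GFF3 emission converts to
# 1-based closed at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; formatted census ratios follow the
#' half-up convention instead (3.675 -> 3.68).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop_input("%s must be a single non-empty string", what)
  if (grepl("[^ACGTacgt]", x))
    stop_input("%s contains non-ACGT characters", what)
  invisible(toupper(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based half-open data.frame (scaffold, start, end) -> GRanges (1-based)
as_granges0 <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("scaffold", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

check_intervals <- function(df, what = "intervals") {
  need <- c("scaffold", "start", "end")
  if (!all(need %in% names(df)))
    stop_input("%s must have columns scaffold, start, end", what)
  if (nrow(df) && any(df$start < 0 | df$end < df$start))
    stop_input("%s contains invalid coordinates (need 0 <= start <= end)", what)
  invisible(df)
}

# transition = purine<->purine or pyrimidine<->pyrimidine substitution
is_transition <- function(a, b) {
  pur <- c("A", "G")
  (a %in% pur) == (b %in% pur) & a != b
}
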