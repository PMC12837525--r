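# LTR-pair divergence and insertion dating. The two LTRs of an element are
# identical at insertion; substitutions accumulated since are read from a
# global alignment of the pair, converted to a distance K (Kimura
# 2-parameter by default) and to an age T = K / (2 r) under a neutral
# substitution rate r per site per year.

#' Global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch with affine gap penalties (a gap of length k costs
#' `gap_open + k * gap_extend`). Traceback ties are broken deterministically,
#' preferring match/substitution over gaps. Transition and transversion
#' counts are taken over ungapped columns only.
#'
#' @param a,b nucleotide strings over ACGT.
#' @param match match score (positive).
#' @param mismatch mismatch penalty (positive magnitude).
#' @param gap_open,gap_extend affine gap penalties (positive magnitudes).
#' @return object of class `pairwise_alignment`: aligned strings `a`, `b`
#'   (with `-` gaps), `score`, `n_ungapped`, `n_transitions`,
#'   `n_transversions`.
#' @export
align_pair <- function(a, b, match = 2, mismatch = 2, gap_open = 10,
                       gap_extend = 1) {
  a <- check_dna(a, "a"); b <- check_dna(b, "b")
  aln <- align_affine_cpp(a, b, match, mismatch, gap_open, gap_extend)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  ungapped <- ca != "-" & cb != "-"
  diff <- ungapped & ca != cb
  ts <- diff & is_transition(ca, cb)
  structure(list(a = aln$a, b = aln$b, score = aln$score,
                 n_ungapped = sum(ungapped),
                 n_transitions = sum(ts),
                 n_transversions = sum(diff & !ts)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: %d columns, score %.1f\n", nchar(x$a),
              x$score))
  cat(sprintf("  ungapped %d, transitions %d, transversions %d\n",
              x$n_ungapped, x$n_transitions, x$n_transversions))
  invisible(x)
}

#' Estimate per-site divergence K from an LTR-pair alignment
#'
#' Computes the transition proportion P and transversion proportion Q over
#' ungapped columns and converts them to a distance:
#' \itemize{
#'   \item K2P: \eqn{K = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)}
#'   \item JC69: \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3}(P+Q))}
#'   \item raw: \eqn{K = P + Q} (uncorrected)
#' }
#' Inputs outside a model's domain (saturated divergence) raise an error
#' naming the model.
#'
#' @param alignment a [align_pair()] result, or any list with
#'   `n_ungapped`, `n_transitions`, `n_transversions`.
#' @param model distance model.
#' @return list of class `divergence_estimate`: `P`, `Q`, `K`, `model`.
#' @export
estimate_divergence <- function(alignment, model = c("K2P", "JC69", "raw")) {
  model <- match.arg(model)
  n <- alignment$n_ungapped
  if (is.null(n) || n <= 0) stop_input("alignment has no ungapped columns")
  P <- alignment$n_transitions / n
  Q <- alignment$n_transversions / n
  K <- k_distance(P, Q, model)
  structure(list(P = P, Q = Q, K = K, model = model),
            class = "divergence_estimate")
}

k_distance <- function(P, Q, model) {
  switch(model,
    K2P = {
      if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
        stop_input("divergence saturated for the K2P model (P=%g, Q=%g)", P, Q)
      -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    },
    JC69 = {
      p <- P + Q
      if (1 - 4 * p / 3 <= 0)
        stop_input("divergence saturated for the JC69 model (p=%g)", p)
      -0.75 * log(1 - 4 * p / 3)
    },
    raw = P + Q)
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("divergence (%s): P=%.5f Q=%.5f K=%.5f\n", x$model, x$P, x$Q,
              x$K))
  invisible(x)
}

#' Insertion time from LTR divergence
#'
#' T = K / (2 r): the two LTRs diverge along two independent lineages since
#' insertion, so K substitutions per site accumulate at rate 2 r per year.
#'
#' @param K per-site divergence (>= 0).
#' @param r substitution rate per site per year; default 1.3e-8.
#' @return insertion age in years.
#' @export
insertion_time <- function(K, r = 1.3e-8) {
  if (any(r <= 0)) stop_input("substitution rate r must be > 0")
  if (any(K < 0)) stop_input("K must be >= 0")
  K / (2 * r)
}

#' Date every intact element of a genome
#'
#' Extracts the 5' and 3' LTR sequences of each annotated intact element
#' (strand-aware), aligns the pair and returns divergence and insertion age.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param intact_annotation intact-element annotation (see
#'   [classify_genome()]).
#' @param model distance model (see [estimate_divergence()]).
#' @param rate substitution rate per site per year.
#' @return data.frame: element_id, superfamily, family, P, Q, K, T_years.
#' @export
date_elements <- function(scaffolds, intact_annotation, model = "K2P",
                          rate = 1.3e-8) {
  ann <- intact_annotation
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    r <- ann[i, ]
    ltr5 <- extract_part(scaffolds, r, r$ltr5_start, r$ltr5_end)
    ltr3 <- extract_part(scaffolds, r, r$ltr3_start, r$ltr3_end)
    est <- estimate_divergence(align_pair(ltr5, ltr3), model = model)
    data.frame(element_id = r$element_id, superfamily = r$superfamily,
               family = r$family, P = est$P, Q = est$Q, K = est$K,
               T_years = insertion_time(est$K, rate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Insertion-time histogram per superfamily
#'
#' Bins insertion ages into half-open intervals `[k w, (k+1) w)` and counts
#' elements per bin and superfamily. Total counts are conserved.
#'
#' @param dates data.frame with `T_years` and `superfamily` columns (as from
#'   [date_elements()]).
#' @param bin_width bin width in years (> 0).
#' @return data.frame: superfamily, bin_start, bin_end, count.
#' @export
insertion_profile <- function(dates, bin_width = 5e5) {
  if (bin_width <= 0) stop_input("bin_width must be > 0")
  if (!nrow(dates))
    return(data.frame(superfamily = character(0), bin_start = numeric(0),
                      bin_end = numeric(0), count = integer(0)))
  bin <- floor(dates$T_years / bin_width)
  tab <- as.data.frame(table(superfamily = dates$superfamily, bin = bin),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  bin0 <- as.numeric(tab$bin)
  out <- data.frame(superfamily = tab$superfamily,
                    bin_start = bin0 * bin_width,
                    bin_end = (bin0 + 1) * bin_width, count = tab$Freq,
                    stringsAsFactors = FALSE)
  out <- out[order(out$superfamily, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
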