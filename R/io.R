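# File interchange. Internal coordinates are 0-based half-open; GFF3 is
# written/read 1-based closed via rtracklayer, BED stays 0-based half-open.

#' Read scaffolds from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_scaffolds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write scaffolds to a FASTA file
#' @param scaffolds named character vector.
#' @param path output file.
#' @export
write_scaffolds <- function(scaffolds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(scaffolds), path)
  invisible(path)
}

part_rows <- function(ann) {
  # flatten intact annotation to one row per part
  parts <- list(
    c("LTR5", "ltr5_start", "ltr5_end"),
    c("internal", "internal_start", "internal_end"),
    c("LTR3", "ltr3_start", "ltr3_end"))
  do.call(rbind, lapply(parts, function(p) data.frame(
    element_id = ann$element_id, scaffold = ann$scaffold,
    start = ann[[p[2]]], end = ann[[p[3]]], strand = ann$strand,
    family = ann$family, superfamily = ann$superfamily, part = p[1],
    stringsAsFactors = FALSE)))
}

#' Write element annotation as GFF3
#'
#' Intact elements are emitted as one `repeat_region` row per element part
#' (LTR5 / internal / LTR3); other loci as a single row with part "LTR".
#' Coordinates are converted from the internal 0-based half-open convention
#' to 1-based closed GFF3.
#'
#' @param loci loci data.frame (element_id, scaffold, start, end, strand,
#'   family, superfamily, status); for intact loci an `intact_annotation`
#'   with part intervals may be supplied.
#' @param path output GFF3 file.
#' @param intact_annotation optional part-level annotation of intact
#'   elements.
#' @export
write_elements_gff3 <- function(loci, path, intact_annotation = NULL) {
  rows <- data.frame(
    element_id = loci$element_id, scaffold = loci$scaffold,
    start = loci$start, end = loci$end, strand = loci$strand,
    family = loci$family, superfamily = loci$superfamily, part = "LTR",
    status = loci$status, stringsAsFactors = FALSE)
  if (!is.null(intact_annotation)) {
    pr <- part_rows(intact_annotation)
    pr$status <- "intact"
    rows <- rbind(rows[rows$status != "intact", , drop = FALSE], pr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$scaffold,
    ranges = IRanges::IRanges(rows$start + 1L, rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "ltrdyn", type = "repeat_region", ID = make.unique(
      paste(rows$element_id, rows$part, sep = ":")),
    element_id = rows$element_id, part = rows$part, family = rows$family,
    superfamily = rows$superfamily, status = rows$status)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read element annotation from GFF3 or TSV
#'
#' Accepts the GFF3 written by [write_elements_gff3()] (or any GFF3 with
#' element_id/part/family/superfamily attributes) and returns the flat
#' part-level table in 0-based half-open coordinates.
#'
#' @param path GFF3 (or tab-separated part table) file.
#' @return data.frame: element_id, scaffold, start, end, strand, family,
#'   superfamily, part, status.
#' @export
read_elements <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    m <- S4Vectors::mcols(gr)
    out <- data.frame(
      element_id = as.character(m$element_id),
      scaffold = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      family = as.character(m$family),
      superfamily = as.character(m$superfamily),
      part = as.character(m$part),
      status = if ("status" %in% names(m)) as.character(m$status)
               else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
  }
  out
}

# reconstruct the per-element intact annotation from part-level rows
parts_to_intact <- function(parts) {
  p <- parts[parts$part %in% c("LTR5", "internal", "LTR3"), , drop = FALSE]
  if (!nrow(p)) return(NULL)
  ids <- unique(p$element_id)
  rows <- lapply(ids, function(id) {
    x <- p[p$element_id == id, ]
    g <- function(part) x[x$part == part, c("start", "end")][1, ]
    l5 <- g("LTR5"); it <- g("internal"); l3 <- g("LTR3")
    data.frame(element_id = id, scaffold = x$scaffold[1],
               start = min(x$start), end = max(x$end),
               strand = x$strand[1], family = x$family[1],
               superfamily = x$superfamily[1],
               ltr5_start = l5$start, ltr5_end = l5$end,
               internal_start = it$start, internal_end = it$end,
               ltr3_start = l3$start, ltr3_end = l3$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a BED file of labeled regions
#'
#' BED is 0-based half-open, matching the package's internal convention;
#' column 4 (name) carries the region class.
#'
#' @param path BED file.
#' @return data.frame: scaffold, start, end, class.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(scaffold = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             class = as.character(S4Vectors::mcols(gr)$name),
             stringsAsFactors = FALSE)
}

#' Write labeled regions as BED
#' @param regions data.frame: scaffold, start, end, class.
#' @param path output BED file.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$scaffold,
    ranges = IRanges::IRanges(regions$start + 1L, regions$end))
  S4Vectors::mcols(gr)$name <- regions$class
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Emits FASTA scaffolds, element GFF3 (truth statuses included), region
#' BED and tab-separated truth tables into a directory.
#'
#' @param bundle a [simulate_genome()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scaffolds(bundle$scaffolds, file.path(dir, "scaffolds.fasta"))
  write_elements_gff3(bundle$truth, file.path(dir, "elements.gff3"),
                      intact_annotation = bundle$intact_annotation)
  write_regions_bed(bundle$regions, file.path(dir, "regions.bed"))
  write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a bundle directory back
#' @param dir directory written by [write_bundle()].
#' @return list with scaffolds, elements (part-level), intact_annotation,
#'   regions, truth.
#' @export
read_bundle <- function(dir) {
  elements <- read_elements(file.path(dir, "elements.gff3"))
  list(scaffolds = read_scaffolds(file.path(dir, "scaffolds.fasta")),
       elements = elements,
       intact_annotation = parts_to_intact(elements),
       regions = read_regions_bed(file.path(dir, "regions.bed")),
       truth = read.delim(file.path(dir, "truth.tsv"),
                          stringsAsFactors = FALSE))
}
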