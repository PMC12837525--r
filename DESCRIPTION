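Package: ltrdyn
Title: Birth and Death Dynamics of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the life cycle of long terminal repeat
    retrotransposons (LTR-RTs) in assembled genomes. Classifies LTR-RT loci
    into intact, solo and truncated states by flanking homology, computes
    solo:intact birth/death ratio statistics with scaffold-length
    stabilization, dates insertions from LTR-pair divergence under the
    Kimura two-parameter model, tests LTR association with structural
    variation classes by interval permutation, classifies tandem and
    proximal gene duplications, filters pseudogene candidates, and
    contrasts gene expression between species-specific and syntenic
    regions. Includes a synthetic genome simulator with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
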