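Package: regapcloser
Title: Gap Closing in Draft Genomes by Robust Regression of Read Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A local assembler that closes N-gaps in draft genome scaffolds
    from paired-end short reads. Reads recruited into a gap are assigned prior
    coordinates from their mates' mapping positions and the library insert
    size; overlaps are detected by prior-guided pairwise alignment and encoded
    as rows of a sparse oriented-incidence linear model whose parameters are
    the read coordinates. Coordinates are estimated by a two-step robust
    procedure (Huber M-estimation via iteratively reweighted least squares,
    followed by a trimmed ordinary least squares refit), which bounds the
    influence of false overlaps caused by tandem repeats and chimeric reads
    and thereby resolves repeat copy numbers that defeat greedy
    overlap-layout-consensus assembly. A quality-aware Bayesian consensus
    with Phred output turns each fitted layout into a gap sequence. Includes
    a paired-read simulator so the whole pipeline is testable without an
    external mapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Matrix,
    methods,
    parallel,
    Rcpp,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
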