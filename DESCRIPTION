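Package: egers
Title: Discovery and Classification of Establishment-Gene Regulatory
    Islands on Conjugative Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for locating establishment-gene
    regulatory sequence (EGeRS) islands on conjugative plasmids of the
    pLS20 family and relatives.  Finds repeated intergenic islands by
    k-mer seeded self-comparison of a circular replicon, characterises
    them (GC anomaly, inverted repeats, sigma-A promoter and dual-heptamer
    operator motifs), classifies each island as EGeRS type 1 or type 2,
    joins islands to their downstream operons to assemble establishment
    regulons, clusters establishment proteins across plasmids with
    Karlin-Altschul statistics, and builds neighbor-joining phylogenies of
    island sequences under the Kimura two-parameter model.  A synthetic
    plasmid generator with full ground-truth tables allows every stage to
    be exercised without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    phangorn,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
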