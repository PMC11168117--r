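Package: ceRNAsponge
Title: Competing Endogenous RNA Network Inference with a Hypergeometric
    Sponge Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA/circRNA-miRNA-mRNA competing endogenous RNA
    (ceRNA) triplets from multi-class RNA-seq count matrices, following the
    workflow used to contrast broody (atrophic) and laying hen ovaries:
    fold-change/FDR gating of differential expression, canonical seed-match
    miRNA target prediction, Spearman and Pearson co-expression filters, a
    hypergeometric test on shared miRNA sponges, and assembly of typed
    regulatory networks with Cytoscape and GraphML export. Ships a
    negative-binomial scenario simulator with planted ceRNA triplets so the
    whole pipeline is testable without sequencing data, plus positional
    lncRNA classification, small-RNA tag filtering/annotation utilities and
    the packaged candidate-gene association table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    igraph,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
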