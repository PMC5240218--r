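Package: pangevo
Title: Bacterial Pangenome Openness, Gene Gain/Loss and Mobilome Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pangenome evolution analysis of bacterial genome sets:
    ortholog family construction by pairwise bidirectional best hits (BBH)
    over a built-in Smith-Waterman backend or precomputed BLAST tabular hits;
    core/accessory/unique partitioning of the gene-family presence/absence
    matrix; rarefaction by random genome combinations with Heap's-law,
    power-law decay and double-exponential curve fitting and openness
    classification; weighted (Sankoff) maximum-parsimony reconstruction of
    gene gains and losses and ancestral genome sizes on a rooted phylogeny;
    threshold-based first-best-hit annotation screens (mobilome,
    cold-adaptation, resistance, transport) with panmobilome partitioning and
    presence/absence clustering; and a synthetic genome-set generator that
    emulates gene-family birth/death along a known tree for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
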