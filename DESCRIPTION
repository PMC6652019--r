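Package: lichenscreen
Title: Multi-Stage Comparative-Genomics Screen for Symbiosis-Relevant Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of the computational screens
    used to nominate symbiosis-relevant genes from a two-partner (fungal
    mycobiont / green-algal photobiont) lichen coculture system: RPKM-based
    coculture/monoculture differential-expression classification, a
    three-predictor consensus secretome call with a transmembrane
    compatibility rule, hypergeometric subgroup enrichment against a
    BLAST-similarity background, sliding-window GC scans with low-GC
    (viral-footprint) region detection and terminal-repeat scaffold joining,
    homolog-cluster detection on annotated genomes, reciprocal-best-hit
    orthology with presence/absence set logic (CiliaCut-style selection),
    and a consensus triplet relative-rate screen for slow/fast evolvers.
    A synthetic-data module generates complete two-genome fixtures with
    planted ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
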