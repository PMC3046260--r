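Package: anchorprobe
Title: Anchor Gene Selection and Riboprobe Design for Compartmental
    Expression Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies compartment-specific 'anchor' genes from
    probeset-by-sample expression matrices of microdissected anatomical
    compartments, using a stringent selection cascade (Welch ANOVA with
    Benjamini-Hochberg correction, fold-change against the median of the
    other compartments, raw-signal floors and cross-compartment
    exclusion), classifies in situ hybridisation validation patterns into
    specific/enriched/ubiquitous/not-detected/non-specific categories,
    and designs transcript-centric riboprobes: 25-mer oligo probes are
    mapped onto transcripts, a 500-800 bp 3'-biased template spanning at
    least 80 percent of the probeset is chosen, a primer pair with a
    T7-tagged reverse primer is designed by a self-contained constraint
    search, and specificity is verified by in-silico PCR. Includes
    seed-deterministic synthetic-data generators with recorded ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
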