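Package: HGTscan
Title: Detection and Verification of Horizontally Acquired Genes in Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects candidate horizontally transferred genes in assembled
    transcriptomes from taxon-partitioned protein homology searches. Computes a
    bitscore-difference HGT index and the legacy alien index per transcript,
    justifies the foreignness threshold with cross-species cumulative index
    curves and their ratio statistic, verifies foreign calls by a five-group
    monophyly classification on support-annotated gene trees, screens out
    contamination with a transcript-to-genome alignment chaining and coverage
    algorithm, and quantifies the metabolic footprint of foreign genes through
    Enzyme Commission colour coding and hypergeometric pathway enrichment with
    Benjamini-Hochberg correction. Includes a fully parameterised synthetic
    data generator that emulates the statistical structure of the inputs so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Phylogenetics, Pathways, Software
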