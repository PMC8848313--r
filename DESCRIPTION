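Package: spanweld
Title: Closing Assembly Gaps with Long Reads at High Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A repeat-aware pipeline for closing gaps in fragmented genome
    assemblies using error-prone long reads. Builds low-complexity, tandem,
    self-alignment and read-coverage repeat annotations, filters read
    alignments down to a reliable set, resolves scaffolding conflicts on a
    four-node-per-contig scaffold graph, computes a reference-guided consensus
    per gap from cropped read pile-ups via local-alignment chaining, validates
    every closed gap by re-mapping the reads, and ships benchmark construction
    (synthetic genomes, CLR-like read simulation, realistic gap introduction)
    together with an evaluator that classifies gaps and measures inserted
    sequence identity and NG50 contiguity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: minimap2 (>= 2.17) on the PATH for whole-assembly read
    mapping; not needed for the pairwise alignment functions.
Config/testthat/edition: 3
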