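Package: famforge
Title: Construction of Viral Protein Family Profile-HMM Databases
Version: 0.1.0
Authors@R: person("famforge", "developers", role = c("aut", "cre"),
    email = "famforge@example.org")
Description: A desk-scale pipeline for building searchable profile-HMM
    databases of viral protein families from metagenomic assemblies.
    Covers consensus selection of high-confidence viral contigs from
    multiple prediction tools, contamination trimming, removal of
    proteins with strong local identity to prokaryotic references,
    dereplication, similarity-graph clustering into protein families
    (native Markov clustering and cohesiveness-greedy algorithms),
    profile hidden Markov model construction with HMMER3 ASCII
    serialization, multi-database annotation consolidation, decoy-FDR
    metaproteomic virion-protein annotation, and benchmarking of
    reference-database augmentation. Includes seeded synthetic-fixture
    generators with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
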