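Package: mcpsc
Title: Multicriteria Protein Structure Comparison
Version: 0.1.0
Authors@R:
    person("MCPSC", "Maintainers", email = "mcpsc@example.org", role = c("aut", "cre"))
Description: A toolkit for multicriteria protein structure comparison (MCPSC).
    Parses C-alpha traces from PDB files, derives residue contact maps, and
    scores structure pairs with pluggable methods: a compression-based
    universal similarity metric (normalized compression distance over contact
    maps), and a built-in rigid-superposition aligner providing a TM-score-like
    similarity and an RMSD distance. Per-method scores are fused into a
    consensus by column-wise min-max normalization and averaging. The pairwise
    job farm can be partitioned and dispatched with random, greedy
    longest-processing-time, or sorted round-robin strategies, and schedules
    can be simulated under fitted polynomial cost models. Clusterings obtained
    by average-linkage hierarchical clustering of consensus distances are
    evaluated against fold labels with the F-measure. A synthetic-data module
    generates labeled fold families of noisy C-alpha chains and simulated job
    runtimes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ape
Config/testthat/edition: 3
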