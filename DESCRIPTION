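Package: netbiomark
Title: Network-Based Gene and miRNA Biomarker Discovery for
    Case-Control Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage biomarker discovery for case-control transcriptomic
    studies. Stage one builds signed-hybrid weighted co-expression networks
    (biweight midcorrelation, soft power, topological overlap) for each
    sample group, detects modules by hierarchical clustering of the control
    network, tests each module's preservation in the case network with
    permutation Z statistics (Z_density, Z_connectivity, Z_summary), and
    ranks hub genes of non-preserved modules by degree in a protein-protein
    interaction network. Stage two selects a minimum set of miRNA regulators
    covering the hub genes via greedy and exact set cover over a bipartite
    miRNA-target network. Includes a seeded synthetic-data generator with
    planted ground truth (a module decorrelated in cases, planted PPI hubs,
    a known-size minimum cover) so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
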