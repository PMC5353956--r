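Package: kpnet
Title: Bow-Tie Hierarchy Decomposition of Kinase-Phosphatase Networks
Version: 0.1.0
Authors@R:
    person("KP-Net", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sorts directed signalling networks (kinase-phosphatase networks
    in particular) into top/core/bottom bow-tie layers with the vertex-sort
    leaf-removal algorithm, quantifies hierarchy with the global reaching
    centrality, generates five degree-constrained randomization null models
    plus Erdos-Renyi graphs, tests motif enrichment and layer-property
    differences (randomization and hypergeometric tests), assesses layer
    robustness to edge noise, fits discrete power laws to degree sequences,
    and predicts kinase-substrate interactions from consensus phosphorylation
    motifs. Includes generators for planted bow-tie and scale-free networks
    so the full toolkit is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
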