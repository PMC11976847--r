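Package: naatools
Title: Network Association Analysis for Pathway Crosstalk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the degree of association between two biological
    pathway networks with a network association algorithm (NAA): node,
    edge and combined association coefficients over a reconstructed
    associated network, optionally weighted by TOPSIS node scores and
    edge betweenness.  Supporting machinery includes topology-indicator
    computation (degree, betweenness, closeness, clustering and
    topological coefficients), entropy-weight + TOPSIS multi-criteria
    node ranking with key-protein selection, a protected k-core
    decomposition that extracts a maximum-coreness target network while
    preserving designated nodes, readers for SIF/TSV edge lists, GMT
    gene sets and protein quantification tables, a differential
    expression filter, a seeded synthetic pathway-pair generator, and a
    config-driven pipeline that replays the DEP -> pathway-pair ->
    key-target workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
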