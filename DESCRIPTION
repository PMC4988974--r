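Package: conetdiff
Title: Comparative Differential Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing weighted gene co-expression networks built
    from paired transcriptomes of related species over a shared ortholog
    space. Implements differential-expression screening with a pooled-variance
    t-test and Benjamini-Hochberg correction, signed soft-thresholded
    adjacencies and topological overlap matrices, module detection by
    average-linkage clustering with a deep-split-controlled tree cut,
    permutation-based module preservation (Z-summary with a random "gold"
    control), targeted-attack robustness indices including a composite
    vulnerability norm across five removal strategies, divergent-hub
    detection from normalized intramodular connectivity, and bipartite
    gene-metabolite network comparison. Includes a synthetic paired-dataset
    generator with planted modules, hub-connectivity divergence and
    metabolite correlations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
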