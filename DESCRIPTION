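Package: groupsil
Title: Silhouette Scores for Predefined Sample Groups in Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes average silhouette (AS) scores for arbitrary predefined
    sample groups on gene expression matrices, using a "1 - Spearman's rho"
    sample distance after zero-count and unique-pattern gene filtering.
    Includes average-linkage hierarchical sample clustering with Newick
    export, a negative-binomial read-count simulator with known
    differentially expressed gene (DEG) structure, an exact
    negative-binomial two-group differential expression test reporting
    P_DEG, P_trueDEG and AUC against simulated truth, and a bootstrap
    harness for replicate-number sweeps relating AS to DE results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite
Suggests:
    ape,
    withr,
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
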