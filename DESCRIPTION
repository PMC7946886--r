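Package: coexhub
Title: Consensus Hub Genes from Weighted Gene Coexpression Networks for Drug-Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks per expression dataset
    (Pearson correlation, soft-threshold power chosen by scale-free topology
    fit, topological overlap, average-linkage module detection, module
    eigengenes, intramodular connectivity), selects top-connectivity hub genes
    per network, forms cross-network consensus hub sets, filters genes by
    directional fold-change consistency across irradiated-versus-control
    conditions, intersects the survivors with a drug-target catalog to produce
    a ranked candidate table, and scores gene-set over-representation with
    Benjamini-Hochberg FDR control. Ships a synthetic multi-dataset expression
    generator with planted modules, hub genes, differential-expression
    directions and a druggable-gene subset, so the whole pipeline is testable
    against ground truth without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    limma
Config/testthat/edition: 3
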