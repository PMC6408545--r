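Package: sig2net
Title: Rank-Based Disease Signatures, Interactome Expansion, and
    Cross-Disease Network Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A cross-disease transcriptomic workflow: rank-based
    subject signatures from expression profiles (fold-change ranking,
    enrichment-score sample distances, percentile similarity graphs,
    popularity-based group consensus signatures), expansion of the
    signature genes over a non-redundant physical protein-protein
    interactome, cross-disease network overlap, hypergeometric gene-set
    over-representation with Benjamini-Hochberg control, and a qPCR
    branch (delta-delta-Ct relative quantification and a rank-product
    permutation test). Ships synthetic-data generators with planted
    ground truth so the whole pipeline can be run and validated
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
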