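Package: cernapipe
Title: Differential Expression, Weighted Co-Expression and ceRNA Network
    Inference for Two-Group RNA-Seq Studies
Version: 0.1.0
Authors@R:
    person("cernapipe", "developers", email = "cernapipe@example.org",
           role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) networks from
    two-group bulk RNA-seq count data for three feature classes (mRNA,
    lncRNA, miRNA). Provides median-of-ratios normalization, a
    fold-change/p-value differential-expression filter, weighted
    lncRNA-mRNA co-expression network construction with soft-threshold
    selection by the scale-free topology criterion, topological overlap
    (TOM) based module detection, and tripartite lncRNA-miRNA-mRNA
    network assembly by correlation screening, shared-miRNA counting and
    hypergeometric testing. Includes a seeded negative-binomial
    simulator with planted differential expression, co-expression
    modules and ceRNA triples, plus Cytoscape-compatible exporters
    (SIF, GraphML, TSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
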