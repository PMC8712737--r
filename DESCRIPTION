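Package: mhnpath
Title: Pathway Prioritization on Multiplex-Heterogeneous mRNA-miRNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes biological pathways against disease-feature risk
    molecule sets (mRNAs and miRNAs) by random walk with restart on a
    multiplex-heterogeneous network (a weighted gene interaction layer, a
    weighted miRNA functional-similarity layer, miRNA-mRNA couplings and
    pathway membership links), truncated singular value decomposition of the
    resulting proximity matrix, and cosine similarity between risk-set and
    pathway embeddings. Pathway ranks are normalized within each source
    database by a size-corrected ranking score and accompanied by seeded
    permutation p-values, with a classical hypergeometric overlap test as
    baseline. Significant pathways are overlaid with competing endogenous RNA
    (lncRNA-miRNA-mRNA) regulations and classified regulatory SNPs to build
    SNP-switching pathway networks, with per-network SNP density and ratio
    statistics and a switch-candidate filter. A seeded synthetic-data
    generator with planted pathway signal makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
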