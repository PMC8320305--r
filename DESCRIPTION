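Package: ironmap
Title: Imaging Transcriptomics of Regional Brain Iron
Version: 0.1.0
Authors@R:
    person("Ironmap", "Developers", email = "ironmap@example.org", role = c("aut", "cre"))
Description: Links regional case-control differences in brain magnetic
    susceptibility (quantitative susceptibility mapping, QSM) to regional
    gene expression. Provides covariate-adjusted regional QSM scoring,
    partial least squares (PLS) regression with spatial spin-permutation
    nulls and bootstrap gene-weight ranking, winner's-curse correction by
    the FDR inverse quantile transformation, gene-set over-representation
    with spatial-null controls, expression-weighted cell-type enrichment,
    and permutation weighting of external differentially-expressed gene
    lists. A synthetic-data module generates cohorts, spatially
    autocorrelated expression matrices, cell-type specificity structures
    and DE lists with planted signal so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    matrixStats,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
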