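Package: counterhub
Title: Counter-Regulated Gene Signatures and Network Focus-Hub Ranking
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A transcriptome-to-target pipeline for disease/treatment expression
    studies. Summarizes probe-level log2 intensities to transcript level via
    quantile normalization and median polish, identifies disease signatures by
    the rank-product statistic with permutation p-values, extracts treatment
    counter-regulated gene sets by K-means binning of fold-change profiles, and
    nominates therapeutic-target hubs by degree-of-connectivity ranking on
    merged, hypergeometric-scored subnetworks of a gene-interaction graph. A
    synthetic-data generator with planted ground truth supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    limma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
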