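Package: morbiclust
Title: Weighted K-Means Clustering of Multimorbidity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments multimorbid populations by jointly clustering binary
    chronic-condition indicators and healthcare-utilization counts with a
    domain-balanced, weighted Hartigan-Wong k-means. Provides a synthetic
    registry-cohort generator with planted cluster structure, the
    multi-start/multi-run minimum-WCSS stability protocol, cluster-number
    selection via elbow, Calinski-Harabasz and simplified-silhouette curves,
    cluster profiling (observed/expected prevalence ratios, utilization
    means, sociodemographic distributions, exact chronic-condition
    portfolios), and a weight-perturbation sensitivity analysis with
    optimally matched confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
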