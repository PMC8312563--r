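Package: wmnet
Title: Graph-Theoretic Analysis of White-Matter Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and graph-theoretic analysis of binary white-matter
    structural brain networks built from streamline-count connectivity
    matrices over a 90-region anatomical parcellation. Implements fiber-number
    thresholding, global small-world parameters (clustering coefficient,
    characteristic path length, local and global efficiency) normalized
    against degree-preserving rewired null ensembles, nodal centralities
    (degree, efficiency, betweenness), rank-based four-criterion hub
    identification, and covariate-adjusted group statistics with Bonferroni
    correction. Ships a synthetic two-group cohort generator that plants
    small-world structure, group-level randomization shifts, and nodal
    deficits, so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
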