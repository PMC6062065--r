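Package: ggiforest
Title: Random-Forest Identification of Gene-Gene Interactions from
    Heterogeneous Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies significant gene-gene interactions (GGIs) from
    two-class (normal vs disease) gene expression profiles in which
    per-condition expression is too heterogeneous for correlation
    thresholds.  Each candidate gene pair is encoded as a 22-dimensional
    vector of class-conditional statistics (means, standard deviations,
    ranges, Welch t statistics, Pearson correlation, and binned mutual
    information), labelled positives are assembled from a curated answer
    set boosted by seed-gene neighbourhood expansion over an interactome,
    class balance is restored by sampling non-interacting negatives, and a
    seedable random forest grown with Gini splits classifies pairs.
    Includes stratified cross-validated evaluation with support-weighted
    metrics, impurity-based feature ranking, predicted-network
    construction with degree-based hub subnetwork extraction, a synthetic
    two-class data generator with planted low-correlation disease pairs,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
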