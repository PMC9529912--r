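Package: mdba
Title: Multidimensional Analysis of Rodent Behavioral Batteries
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Multidimensional analysis of rodent behavioral test batteries:
    sex-aware z-standardization, principal component analysis, k-means
    clustering in principal component space, and validation of clusters
    against genotype, yielding a composite behavioral severity score (PC1).
    Includes the surrounding experiment suite (single-measure ablation,
    exhaustive measure-subset scans, bootstrap sample-size curves,
    false-positive null controls, per-cohort runs, and three-arm treatment
    analysis in 1-PC space) together with self-contained statistical
    primitives (two-way ANOVA, Tukey-Kramer post hoc, Fisher's exact test,
    Grubbs' outlier test) and a calibrated synthetic cohort generator so the
    full pipeline can be exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
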