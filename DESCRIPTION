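Package: spathet
Title: Spatial Heterogeneity Indicators from Multi-Lesion PET/CT
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies inter-lesion (spatial) heterogeneity in multi-lesion
    abdominopelvic PET/CT studies, e.g. high-grade serous ovarian cancer with
    peritoneal spread. Computes 8 conventional per-lesion features (CT value,
    axis lengths, voxel count, TLG, SUVmean/peak/max) aggregated by 13
    patient-level statistics into 104 indicators, plus 3 texture-cluster
    indicators (cluster site entropy, cluster diversity, cluster dissimilarity
    SD) from voxel-level Haralick maps, Gaussian-mixture subregion clustering
    and inter-site dissimilarities. Includes a synthetic multi-lesion phantom
    cohort generator with known ground-truth heterogeneity, a gradient-boosted
    tree classifier with stratified cross-validation and a full metric panel,
    Spearman association and ICC reproducibility statistics, and minimal
    NIfTI-1 volume I/O.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
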