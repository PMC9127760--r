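Package: ReHoMVPA
Title: Regional Homogeneity Mapping and Multivariate Pattern
    Classification for Resting-State fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxel-level local functional connectivity (regional
    homogeneity, Kendall's coefficient of concordance over 27-voxel
    neighborhoods) computed from preprocessed 4D BOLD volumes, followed
    by leave-one-subject-out multivariate pattern classification (linear
    support vector machine and binary/multiclass Gaussian process
    classifiers), permutation-based significance testing of performance
    and voxel-wise discriminative weights with cluster-extent
    thresholding, and covariate-adjusted partial Pearson correlation of
    cluster-mean values against symptom severity. Includes a synthetic
    three-group cohort generator with implanted regional temporal
    coherence for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
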