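Package: mvpaFuse
Title: Cross-Decoding, Temporal Generalization and EEG-fMRI Fusion for
    Multivariate Neural Pattern Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multivariate pattern analysis (MVPA) toolkit for studying
    where and when stimulus attributes are represented in neural
    measurements. Implements cross-classification of one experimental
    factor across another (for example object location across object
    category) with linear support vector machines on pseudo-trial
    averages, multivariate noise normalization, region-of-interest and
    searchlight decoding in voxel and EEG sensor space, time-resolved
    decoding and temporal generalization with a signed peak-to-diagonal
    statistic, representational dissimilarity vector (RDV) fusion of EEG
    and fMRI, and group-level inference (Wilcoxon signed-rank tests,
    Benjamini-Hochberg false discovery rate control, subject-level
    bootstraps and label-shuffle nulls). A synthetic-data generator with
    planted location and category signals makes the full pipeline
    testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, e1071, jsonlite, RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
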