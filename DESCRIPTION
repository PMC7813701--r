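Package: voxnorm
Title: Voxel-Wise Normative Gray Matter Atrophy Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds age- and sex-specific normative gray matter templates
    from a cohort of preprocessed T1-weighted MRI scans and computes
    voxel-wise z-score atrophy maps for single subjects. Provides a
    simplified, self-contained voxel-based morphometry preprocessing chain
    (Gaussian-mixture tissue segmentation, affine spatial normalization,
    Jacobian modulation, Gaussian smoothing), sliding-window mean/SD
    template construction, z-map thresholding and color fusion with the
    structural scan, an alignment quality check, a synthetic brain phantom
    generator with programmed aging and injectable focal atrophy, and
    paired diagnostic-test statistics (sensitivity, specificity, McNemar's
    test) for reader studies comparing map-based and visual-scale atrophy
    assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
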