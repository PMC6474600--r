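Package: petrim
Title: Rim-Based Quantitative Imaging Features for FDG-PET Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes standard and rim-based quantitative imaging features from
    FDG-PET standardized-uptake-value (SUV) volumes with lesion segmentations:
    SUVmax, SUVpeak, SUVmean, metabolic tumor volume (MTV), total lesion
    glycolysis (TLG), distributional statistics, grayscale-quarter features,
    the rim average (RA) of a 2-voxel-wide shell surrounding the lesion, and
    standardized added metabolic activity (SAM). Features can be normalized by
    mean liver uptake, differenced between pre- and post-treatment scans, and
    screened against disease-free survival with per-standard-deviation
    univariate Cox regression, Harrell's c index, Benjamini-Hochberg false
    discovery rates, and Kaplan-Meier tertile curves. Includes synthetic
    phantom and cohort generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    MASS,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
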