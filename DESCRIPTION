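Package: yrrta
Title: Yearly Rate of Relative Thalamic Atrophy from Paired MRI Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Planimetric (2D) and volumetric (3D) quantification of the
    yearly rate of Relative Thalamic Atrophy (yrRTA), a longitudinal
    deep-gray-matter atrophy index that relates annualized thalamic
    shrinkage to annualized ventricular enlargement between two MRI
    timepoints. Reads paired-timepoint NIfTI segmentation label volumes
    or pre-measured CSV tables, selects the reference axial slice,
    measures thalamic and ventricular areas and volumes, computes the
    yrTA, yrVE and yrRTA rates, maps them to a qualitative risk
    classification, and ships a synthetic brain-phantom generator with
    exact voxel-level ground truth for end-to-end verification and
    cohort simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
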