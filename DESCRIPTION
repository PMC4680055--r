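Package: segrank
Title: Evaluation and Ranking of Brain Tissue Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation framework for (semi)automatic gray matter, white
    matter and cerebrospinal fluid segmentations of 3T brain MRI.
    Reads candidate and reference label volumes from NIfTI, harmonises an
    eight-structure annotation scheme into the three scored tissue
    classes (excluding cerebellum and brainstem), and computes three
    complementary measures per anatomical component (GM, WM, CSF, brain,
    intracranial volume): the Dice overlap coefficient, the 95th
    percentile Hausdorff boundary distance in millimetres on anisotropic
    voxel grids, and the absolute volume difference. Per-case results are
    aggregated into per-method means and standard deviations, and methods
    are ranked by a sum-of-ranks score with a standard-deviation based
    tie-break, reproducing the leaderboard construction used by
    multi-method segmentation challenges. A synthetic nested-ellipsoid
    phantom generator with controlled corruptions (relabel, shift,
    dilate) makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
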