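Package: hemiacm
Title: Hemisphere-Restricted Anatomical Connectivity Mapping on Synthetic
    Diffusion Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic streamline tractography seeded in every
    white-matter voxel of a single hemisphere, with mid-sagittal exclusion,
    voxel-wise streamline counting into anatomical connectivity maps (ACM),
    and downstream lateralization analysis. Includes a multi-shell
    diffusion-weighted phantom generator with crossing fibre bundles and
    focal lesions, shell intensity calibration, weighted-least-squares
    diffusion tensor fitting (FA/MD), ROI and lateralization-index
    summaries, slice-wise asymmetry profiles, covariate-adjusted group
    statistics, and voxel-wise permutation testing with threshold-free
    cluster enhancement (TFCE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
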