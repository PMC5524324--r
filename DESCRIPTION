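Package: marmotbm
Title: Tensor-Based Morphometry of Synthetic Marmoset Brain Phantoms
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale tensor-based morphometry (TBM) pipeline for small-cohort
    non-human-primate neuroimaging studies, exercised end to end on synthetic
    T2-weighted marmoset head phantoms with known, injected regional atrophy.
    Provides phantom cohort simulation (multi-echo T2 signal model, labelled
    atlas geometry, calibrated atrophy fields), manual-style ROI volumetry and
    cortical thickness with group statistics (independent t-tests, two-way
    ANOVA with Sidak follow-up, Cohen's d), rigid/similarity and fluid
    (demons-type) registration, Jacobian determinant maps, voxel-wise
    exhaustive-permutation t-tests with Benjamini-Hochberg FDR masking, and
    noncentral-t / Fisher-z power analysis for small group sizes. Volumes are
    read and written as NIfTI-1 with JSON sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
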