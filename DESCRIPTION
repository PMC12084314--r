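Package: dbmorph
Title: Deformation-Based Morphometry and Crispant Screen Statistics for
    Larval Zebrafish Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-volume morphometry for registered larval zebrafish brain
    cohorts: log-Jacobian-determinant (LJD) maps from atlas-to-subject
    displacement fields, atlas-label region volumetry, voxelwise two-group
    and two-way ANOVA statistics with cluster-extent and bilateral-symmetry
    filtering, ROI replication and rescue testing. Companion statistics for
    CRISPR crispant screens: guide efficiency from capillary-electrophoresis
    fragment traces (wildtype peak area fraction), two-experiment
    differential-expression overlap with Fisher exact enrichment, and
    relative qPCR quantification by the 2^(delta Cp) method. Includes a
    synthetic-data generator (labeled symmetric phantom atlas, smooth
    invertible deformation fields with programmable localized contraction,
    electropherograms, gene tables, qPCR plates) so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    RNifti,
    rlang,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
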