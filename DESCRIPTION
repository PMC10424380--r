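Package: chemomap
Title: Chemogenetic fMRI Activation Mapping and Phantom Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for pharmacological (chemogenetic) fMRI
    experiments in which a designer-receptor ligand is injected mid-scan
    and the evoked BOLD response is mapped brain-wide. Provides baseline
    percent-signal-change normalization, mask-aware Gaussian smoothing,
    a voxel-wise activation-phase area-under-the-curve statistic with
    group t-tests and Benjamini-Hochberg false discovery rate control,
    sigmoid response-curve fitting of region-of-interest time courses
    with pairwise comparison matrices, conjunction analysis of two
    stimulation experiments, and a deterministic synthetic 4D phantom
    cohort generator with ground-truth manifests for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
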