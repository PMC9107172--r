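Package: gliomaSeg
Title: Symmetry-Based Region Growing and Fuzzy C-Means Brain Tumor
    Segmentation with Phantom-Based Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classical single-modality brain tumor segmentation for
    skull-stripped NIfTI MRI, including low-resolution clinical-style
    volumes with non-contiguous slices. Implements a hemisphere-symmetry
    seeded region-growing pipeline (vertical alignment, midline split,
    mirrored subtraction, contrast stretching, connected growth) and a
    slice-wise fuzzy C-means pipeline with small-object cleanup, together
    with Dice, boundary Hausdorff and volume evaluation, and a synthetic
    brain phantom generator with ground-truth labels for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'gliomaSeg-package.R'
    'AllGenerics.R'
    'utils-image.R'
    'io.R'
    'align.R'
    'asymmetry.R'
    'rg.R'
    'fcm.R'
    'metrics.R'
    'phantom.R'
    'cli.R'
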