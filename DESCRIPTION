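Package: VoteSeg
Title: Majority-Voting Ensemble Fusion and Evaluation for 3D Tooth Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for 3.5D ensemble segmentation of teeth on cone-beam CT
    volumes. Decomposes a 3D scan into axial/coronal/sagittal slice stacks,
    three-channel 2.5D slabs and 3D patches, trains small U-Net predictors,
    fuses aligned binary prediction masks by per-voxel majority voting
    (including nested 3.5D voting schemes), post-processes masks by binary
    morphological opening with a spherical structuring element, and evaluates
    predictions against ground truth with slice-based confusion counts, six
    derived metrics, fourfold cross-validation folds and nonparametric
    statistics. Includes a synthetic dental-phantom generator with
    controllable prediction degradation for end-to-end validation, plus
    NIfTI/NRRD/DICOM volume input and metallic-dental-burden screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    mgcv,
    EBImage,
    nortest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'dicom.R'
    'preprocess.R'
    'views.R'
    'morphology.R'
    'voting.R'
    'unet-layers.R'
    'unet.R'
    'metrics.R'
    'stats.R'
    'phantom.R'
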