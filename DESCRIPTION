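Package: brainstate
Title: Temporal Brain-State Decoding for Block-Design fMRI Across Acquisition Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivoxel pattern analysis of block-design functional MRI time
    series acquired with BOLD, perfusion-weighted arterial spin labeling (ASL)
    and arterial volume-weighted arterial spin tagging (AVAST) contrasts.
    Provides surround subtraction of control/tag series, Gaussian spatial
    smoothing, voxel-wise temporal normalization and brain masking; assembles
    labeled example sets with optional exclusion of task/rest transition
    frames; trains a linear soft-margin support vector machine for task-vs-rest
    classification across runs; and localizes discriminative voxels by a
    label-permutation test on the normalized SVM weight map. A synthetic-data
    module generates multi-modality 4D block-design series with known ground
    truth so the full pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    jsonlite,
    RNifti,
    tibble,
    generics,
    ggplot2,
    rlang,
    utils
Suggests:
    testthat (>= 3.0.0),
    dplyr
Config/testthat/edition: 3
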