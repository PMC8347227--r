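Package: bcitransfer
Title: Cross-Subject Transfer Learning for Motor-Imagery EEG with
    Stepwise Kernel Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cross-subject transfer learning in motor-imagery
    brain-computer interfaces. Implements bi-domain topographic feature
    extraction from multi-channel EEG (common spatial patterns and
    complex-Morlet wavelet energy rendered as scalp topograms), a
    Deep-and-Wide convolutional classifier with per-topogram branches
    trained by Adam on a mean-squared-error loss, stepwise Gaussian-kernel
    matching that fuses EEG feature embeddings with psychological
    questionnaire scores through centered kernel alignment, tensor-product
    kernel fusion and kernel PCA, similarity-based source-subject
    selection, and fine-tuning-based parameter transfer to poor-performing
    subjects. Includes a seeded synthetic cohort generator emulating
    lateralized mu/beta event-related desynchronization with
    subject-varying skill, plus HDF5/CSV/EDF readers and writers and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
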