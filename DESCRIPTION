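Package: invbase
Title: Inverse-Filter Baseline Removal for Subject-Independent EEG Emotion Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Removes a subject's resting-state baseline from trial EEG by
    point-wise spectral division (inverse filtering), extracts band-wise
    spectral features (theta/alpha/beta/gamma mean and variance) over
    averaged time windows, and evaluates valence/arousal classification
    under stratified k-fold and leave-one-subject-out protocols against
    subtractive and no-correction baselines. Includes a synthetic EEG
    generator with subject-specific spectral gain profiles so the
    subject-independence claim is testable without restricted datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
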