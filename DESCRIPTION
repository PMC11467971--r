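Package: cspmi
Title: Spatial-Filter Decoding of Exoskeleton-Assisted Motor Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how temporal and spectral segmentation interact
    with Common Spatial Pattern (CSP) layers when decoding motor imagery
    during exoskeleton-assisted passive movement. Implements classic CSP,
    filter-bank CSP with mutual-information feature selection (FBCSP), and a
    two-layer spatial-spectral variant (FBCSSP); zero-phase Butterworth
    band-pass preprocessing with sliding-window and static temporal
    segmentation; linear discriminant classification under leakage-safe
    grouped cross-validation with accuracy and false-positive-rate metrics;
    and the between-method significance analysis (Shapiro-Wilk, Levene,
    directional two-sample t-tests). A protocol-faithful synthetic EEG
    generator with known ground truth (source mixing, event-related
    desynchronization) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
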