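Package: bundleScan
Title: Axon Bundle Activation Thresholds from Multi-Electrode Array
    Stimulation Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automatic detection of axon bundle activation for epiretinal
    prostheses. Given repeated single-electrode stimulation recordings on a
    rectangular multi-electrode array, the package estimates for every
    stimulating electrode the lowest current amplitude that evokes
    bidirectional axonal activity reaching at least two borders of the
    array. It implements the five-step detection pipeline (electrical
    artifact subtraction, spike-time extraction, a chi-squared spike-time
    variance test, monotone pruning across amplitudes, and the two-border
    rule), a synthetic stimulation-scan simulator with ground-truth bundle
    thresholds, agreement metrics against reference thresholds, and an
    HDF5-based scan container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'amplitude-grid.R'
    'detection-config.R'
    'thresholds.R'
    'scan-recording.R'
    'scan-io.R'
    'detection.R'
    'simulator.R'
    'validation.R'
    'study.R'
    'cli.R'
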