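Package: cvrkit
Title: Cerebrovascular Reactivity Mapping from BOLD fMRI and CO2 Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of cerebrovascular reactivity (CVR)
    from BOLD fMRI. Extracts an end-tidal CO2 (EtCO2) curve from a raw
    capnogram using dual peak-detection algorithms (scale-space and
    smooth-cross), temporally aligns the EtCO2 regressor to the BOLD time
    course by two-step residual minimisation, and computes whole-brain,
    regional and voxel-wise CVR maps in %/mmHg together with hemodynamic
    temporal-shift maps. A resting-state mode derives a low-frequency
    whole-brain reference signal in place of EtCO2 and produces relative CVR
    maps. Includes a synthetic phantom generator (capnograms, CO2-task and
    resting-state BOLD series with known ground truth) so that every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    oro.nifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
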