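Package: stereoframe
Title: Stereotactic Frame Registration and Trajectory Planning from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frame-based stereotactic planning from head CT. Detects
    the vertices of N-shaped localizer plates on a Leksell-type frame by
    layerwise maximum-intensity tracking from rough user seeds, rigidly
    registers the detected fiducials to the canonical frame position with the
    Kabsch algorithm, converts image (RAS) coordinates to Leksell frame
    coordinates, and computes the arc and ring angles of a target-entry
    trajectory. Includes a synthetic CT phantom generator with known ground
    truth for end-to-end validation, agreement statistics (per-axis deviations,
    paired t-tests, Bland-Altman limits) for comparing plan sets, and a
    command-line pipeline for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
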