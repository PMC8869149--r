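Package: stormsba
Title: Structure-Based Size Estimation for Single-Molecule Localization
    Microscopy
Version: 0.1.0
Authors@R: person("stormsba", "developers", email = "stormsba@example.org",
    role = c("aut", "cre"))
Description: Estimates the physical size of fluorophore-labeled structures
    from single-molecule localization microscopy (STORM/PALM) data by
    least-squares fitting the convolution of a geometric structural function
    with a Gaussian localization kernel to line profiles of localization
    counts (structure-based analysis, SBA), alongside the classical full
    width at half maximum baseline. Includes cluster detection, principal
    axis profile extraction, a synthetic STORM data generator with both a
    localization-level and a frame-level (PSF rendering plus 2D Gaussian
    spot localization) path, localization table input/output, and a command
    line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
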