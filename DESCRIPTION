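Package: nmrcube
Title: Multivariable Analysis of Protein NMR Peaklist Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loads curated two-dimensional NMR peaklists from several common
    text dialects (Sparky, NMRPipe, CCPN Analysis v2, NmrView) into a
    three-axis experimental data structure, extracts ordered series along any
    axis, and computes per-residue derived parameters: combined chemical
    shift perturbations, peak height and volume ratios, deviations of
    observed paramagnetic relaxation enhancement profiles from a random-coil
    prediction, and Gaussian-smoothed profiles.  Continuous titration series
    can be fitted per residue to binding isotherms to estimate dissociation
    constants.  Results are written as comma-separated tables, molecular
    viewer attribute files and publication-style figures, all driven by a
    single JSON run configuration, with no GUI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
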