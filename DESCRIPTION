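Package: smlmpipe
Title: Simulation and Analysis Pipeline for In-Resin Single-Molecule
    Localization Microscopy with Electron-Microscopy Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule localization microscopy (SMLM) data
    and its correlation with transmission electron microscopy images.
    Includes a forward simulator for photo-switching fluorophore movies with
    EMCCD noise, maximum-likelihood Gaussian point-spread-function fitting
    with sliding-window background subtraction, localization-accuracy
    estimation from nearest-neighbor distances in adjacent frames, local
    density and Nyquist-limited structural-resolution estimation from
    k-nearest-neighbor distances, density-coded super-resolution rendering,
    and control-point registration (similarity or affine) between SMLM and
    electron-microscopy coordinate systems with overlays and line profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    RANN,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
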