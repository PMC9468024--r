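Package: icescreen
Title: Ice-Quality Screening of Cryo-EM Grids from Interferometric Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated screening of plunge-frozen cryo-EM grids from
    three-wavelength reflected-light interferograms. Detects grid squares
    (tiles) against the metal grid bars, estimates and corrects the in-plane
    grid rotation with a radon-transform criterion, classifies every square
    into five ice-quality classes (bad, too thin, optimal, thicker, too
    thick) with a confidence value, and validates the class-to-thickness
    relationship with absolute ice-thickness maps computed from
    energy-filtered/unfiltered electron-microscope image pairs via the
    zero-loss log-intensity ratio. Because raw screening images of this kind
    are rarely deposited, the package includes a physics-based
    synthetic-scene generator (thin-film interference over standard mesh
    geometries with class-conditioned ice-thickness fields and defects) that
    provides labelled training and validation data for every stage, plus a
    watch-folder batch mode for unattended analysis during acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
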