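Package: caflow
Title: Blood-Stasis Hemodynamics for Occluded Coronary Arterial Fistulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pulsatile hemodynamics and blood-stasis (washout)
    modelling for coronary arterial fistulas with terminal aneurysms.
    Generates idealized two-dimensional fistula-with-aneurysm geometries on
    labelled structured grids, couples a staggered finite-volume
    incompressible flow solver to lumped-parameter outlet models (Windkessel
    RCR at the aortic outlet, a coronary lumped-parameter network at coronary
    outlets), transports an old-blood volume fraction through the periodic
    flow to quantify stasis, and computes the thrombosis metrics used to
    compare virtual occlusion strategies: proportion and area of high
    oscillatory shear index (OSI), old blood volume fraction (OBVF) and old
    blood volume (OBV), plus time-averaged wall shear stress (TAWSS) and
    aortic flow-split diagnostics. Includes the OBV-based decision rule for
    recommending a proximal or distal occlusion position.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
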