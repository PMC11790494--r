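Package: guvrafts
Title: Quantitative Analysis of DNA-Nanoraft-Driven GUV Remodelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how membrane-bound, reconfigurable DNA nanorafts
    remodel giant unilamellar vesicles (GUVs) and gate cargo transport, driven
    entirely by a synthetic confocal-microscopy data generator so every stage is
    testable without experimental data. Implements automated equatorial-slice
    membrane tracing with normalized local-curvature statistics (SD_k) and
    deformation classification; one-component 2D diffusion fitting of
    fluorescence correlation spectroscopy (FCS) curves with detection-volume
    calibration and raft surface-density conversion; raft-binding kinetics,
    cargo influx (relative import level), FRAP gating and molecular-weight
    cut-off summaries; and a hard-rectangle Monte Carlo simulator with an
    in-place shape-transformation protocol and local tetratic order metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
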