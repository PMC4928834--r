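Package: rodSPT
Title: Single-Particle Tracking of Membrane Microdomains on Rod-Shaped Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of fluorescent membrane-protein
    microdomains (e.g. bacterial flotillins) tracked on the curved surface
    of rod-shaped cells.  Provides cell-frame coordinate transforms and
    drift correction, weighted mean-squared-displacement fitting and
    covariance-based diffusion estimation with per-axis decomposition and
    a cylinder-projection correction, a membrane encounter-time model with
    a Monte-Carlo first-passage oracle, photobleaching step detection and
    subunit counting, focus-size (50%-intensity width) measurement and
    colocalization scoring, plus synthetic-data generators with known
    ground truth for every pipeline stage: Brownian walks on a cylinder
    observed in noisy 2D projection, rendered movies, bleaching traces and
    focus images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    xml2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
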