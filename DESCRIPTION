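Package: cableflock
Title: Quantifying Bacterial Flocking Around Cable Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the behaviour of motile bacteria that flock
    around oxygen-connected cable bacteria filaments in sediment microcosms.
    Implements video-based cell detection (stack-median background
    subtraction, thresholding, particle gating by size and circularity),
    nearest-neighbour track linking with speed-change splitting and validity
    filters, distance and speed statistics relative to a manually keyframed
    filament trace, dispersal-time measurement after laser cutting,
    single-cell Raman cytochrome redox band quantification with paired
    quality control, and a flux-balance estimate of the soluble electron
    shuttle concentration and turnover time. A synthetic flocking simulator
    with known ground truth (run-and-tumble cells with distance-dependent
    attraction, rendered noisy image stacks, paired Raman spectra) makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
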