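Package: aznano
Title: Active-Zone Nanotopology from Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dSTORM/SMLM localization tables of presynaptic
    active zones: localization table input/output and intensity/ROI filtering,
    NeNA localization-precision estimation from consecutive-frame nearest
    neighbours, two-level HDBSCAN clustering (active zones, then Bruchpilot
    subclusters), adaptive alpha-shape morphometry with an automatic alpha
    selection rule, Ripley's H-function nanocluster radius estimation without
    edge correction, rank-based group statistics, and a seeded synthetic
    localization-scene generator with per-dye presets (AF647, CF568, CF583R)
    and full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    interp,
    FNN,
    sp,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
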