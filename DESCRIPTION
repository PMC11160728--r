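Package: loopquant
Title: Quantitative Analysis of SMC Loop-Extruder Dynamics During Mitotic Exit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Condensin, Cohesin and CTCF dynamics on
    chromatin as cells rebuild interphase genome architecture after mitosis.
    Implements FCS-calibrated copy-number estimation, FRAP and spot-bleach
    photobleaching kinetics with immobile fractions, per-megabase chromatin
    occupancy tables, STED spot segmentation and colocalization with
    dimer-fraction inference, chromatin-trace distance and contact analysis,
    and a stochastic two-species 1D loop-extrusion simulator with CTCF
    boundary stalling and encounter-induced pairing. A synthetic-data module
    generates every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
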