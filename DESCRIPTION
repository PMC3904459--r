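Package: rangemod
Title: Range Modulation for Proton Spread-Out Bragg Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: One-dimensional water-phantom simulation of proton
    spread-out Bragg peaks (SOBPs). Pristine Bragg peaks follow a
    Bragg-Kleeman stopping-power kernel with Gaussian range spread; SOBP
    plateau weights are fitted by non-negative least squares; an analytic
    hyperbolic-tangent distal-edge model assigns each pristine peak an
    elevated relative biological effectiveness (RBE) saturating beyond
    its dose maximum. Implements two-way and three-way range-modulation
    schemes that split a beam across slightly different ranges to smear
    the distal falloff, and metrics quantifying plateau flatness,
    effective range, biologically effective range extension and the
    distal RBE hotspot.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    stats,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
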