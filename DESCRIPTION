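Package: vinkin
Title: Mechanokinetic Analysis of Force-Dependent Talin-Vinculin Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-molecule mechanokinetics of the talin-vinculin interaction:
    Bell-Evans force-dependent rate laws, a kinetic Monte Carlo simulator of the
    weak-to-mature binding scheme that emits magnetic-tweezers-like extension
    traces, change-point step detection and dwell-time extraction, log-binned
    ("square-root") dwell-time histograms with exponential-mixture fitting,
    maturation-timescale estimation, Hill-Langmuir actin-bundling dose-response
    fits with a shared saturation plateau, and focal-adhesion geometry
    quantification (equivalent cell radius, central/peripheral classification,
    background-subtracted intensity) on segmented masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    EBImage
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
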