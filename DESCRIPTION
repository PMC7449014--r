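Package: eetmorph
Title: Separating Morphological from Physiological Effects on Mediated
    Extracellular Electron Transfer in Rod-Shaped Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much of an observed difference in mediated
    extracellular electron transfer (EET) rate between two cyanobacterial
    cultures is attributable to cell-morphology change versus physiological
    or metabolic change. Implements spherocylinder (rod-cell) stereology,
    a liquid-to-cell mass-transfer correlation for suspended
    microorganisms, inversion of the mass-transfer-limited mediator
    reduction-rate law for the bulk-to-surface concentration difference,
    the decoupled length-derivative of the reduction rate, and the
    sigmoid-transformed Morphology Effect Ratio (MER), together with the
    supporting measurement pipeline: moment-ellipse morphometry of
    fluorescence images, ferricyanide-assay slope rates, Gompertz growth
    fitting, weighted population statistics, first-order error
    propagation, and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
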