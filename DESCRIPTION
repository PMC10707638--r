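Package: bonedma
Title: Viscoelastic Modelling of Alveolar Cancellous Bone from Dynamic
    Mechanical Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the dynamic viscoelasticity of human cancellous bone in
    the alveolar process as a function of bone mineral density (BMD).
    Implements the generalized Maxwell (Prony series) material model in the
    time and frequency domains, a BMD-parameterised constitutive model for
    the storage and loss moduli, constrained multi-start nonlinear
    least-squares identification from dynamic mechanical analysis (DMA)
    frequency sweeps, the equilibrium-modulus-BMD power law, and a synthetic
    nine-sample DMA study generator so the whole pipeline can be exercised
    without access to cadaveric specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
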