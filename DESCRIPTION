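Package: cctamar
Title: Motion-Artefact Reduction for Coronary CT Angiography with a
    Conditional Adversarial Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing cardiac-motion artefacts in coronary CT
    angiography (CCTA) cross-sections with a conditional adversarial
    image-to-image model. Provides a synthetic vessel-phantom simulator with
    parameterized directional motion smearing, Hounsfield-unit preprocessing
    and residual-based artefact ROI extraction, a Res-UNet generator and a
    70x70 patch discriminator trained with an adversarial plus weighted-L1
    objective, and an objective quality-evaluation suite (global SSIM, Dice
    similarity coefficient, vessel circularity) with normality-gated paired
    statistical comparison. The neural-network layers, backpropagation and
    Adam optimizer are implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
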