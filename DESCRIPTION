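Package: texkin
Title: Texture-Tensor Kinematics for Epithelial Tissue Deformation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies epithelial tissue deformation from segmented time-lapse
    imaging using texture tensors built from cell-center half-links. Implements
    normalization variants of the texture tensor, pixel-based second moments,
    the half-link strain-rate decomposition of the total tissue strain into
    cell shape change, rearrangement, division and apoptosis contributions, and
    checks of the kinematic equation for the coarse-grained cell-shape tensor
    and of the cell-number-density balance. Includes FFT cross-correlation
    particle image velocimetry, globally optimal cell tracking with division
    and apoptosis detection, Lagrangian region-of-interest bookkeeping, and a
    synthetic polygonal-tissue simulator (affine and smooth flows, T1
    transitions, divisions, T2 removals) that provides exact ground truth for
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deldir,
    clue,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
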