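Package: cmavib
Title: Concordant Mode Approach for Harmonic Vibrational Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonic vibrational analysis in natural internal coordinates
    (NICs) with the Wilson GF method, and the Concordant Mode Approach (CMA)
    for composing a high-level (Level A) force field in the normal-mode basis
    of a cheaper Level B theory. Includes the convergent CMA-2 protocol that
    selects off-diagonal force constants through the dimensionless xi
    diagnostic computed from an auxiliary Level C force field,
    fourth-order-accurate finite-difference force-constant assembly with
    symmetry enforcement, iterative back-transformation of normal-mode
    displacements to Cartesian geometries, total energy distribution (TED)
    mode characterization, benchmark residual statistics, and a synthetic
    generator of correlated Level A/B/C force-field triples for end-to-end
    testing without an electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
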