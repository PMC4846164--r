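Package: rrscan
Title: Quasi-Harmonic Entropy and Rigid-Residue-Scan Analysis of Protein Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for covariance-based analysis of protein conformational
    ensembles: quasi-harmonic mode extraction and configurational entropy from
    the mass-weighted coordinate covariance, per-residue entropy decomposition
    from sub-covariance blocks, cross-correlation maps, principal-component
    projections with mode-coherence validation, and the bookkeeping statistics
    of a rigid-residue scan (delta-S, delta-delta-S, key-residue screening,
    response maps, confidence intervals).  Includes a synthetic harmonic-model
    generator (elastic-network construction, rigid-residue constraint
    emulation, two-state mean shifts) with closed-form entropies so that every
    analysis stage can be validated against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
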