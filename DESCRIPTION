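Package: npmhub
Title: Nucleophosmin Hub Interactions: NoLS Scanning, Binding Fits and
    Coarse-Grained Peptide Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the recognition of nucleolar localization
    signals (NoLS) by the N-terminal domain of nucleophosmin (NPM1).
    Provides sliding-window basic-charge scanning of protein sequences,
    quadratic and hyperbolic equilibrium-binding models for fluorescence
    titrations with replicate-aware dissociation-constant estimation, a
    coarse-grained charged-bead representation of receptors and peptides
    with screened-Coulomb surface-potential, acidic-patch and cavity
    analysis, a hierarchical divide-and-conquer peptide docking protocol
    (tripeptide enumeration, simulated-annealing pose search, RMSD
    clustering, template-biased hexamer and whole-peptide docking, gradient
    minimization, salt-bridge reporting), and trajectory RMSD analytics
    (Kabsch superposition, time series, per-residue profiles). Synthetic
    generators for titrations, crown-shaped pentamer-like receptors and
    anchored peptide trajectories make the whole pipeline exercisable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
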