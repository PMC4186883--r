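Package: ssbridge
Title: Disulfide Bond Conformational Landscapes Under Tensile Force
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of how tensile force reshapes the conformational
    landscape of disulfide bonds. Provides constant-force (isotensional)
    torsional Metropolis Monte-Carlo sampling of disulfide model compounds
    (diethyl disulfide, cystine, and the force-bearing path of a
    disulfide-bridged polypeptide loop), periodic two-dimensional
    (chi1, chi2) probability landscapes with Boltzmann inversion to free
    energy surfaces, open/closed conformer statistics, a PDB disulfide
    geometry survey (SSBOND-aware, with per-protein-class summaries), a
    stress-strain "ruler" calibrating mean Calpha-Calpha distance against
    force with monotone inverse lookup, a Bell-model rate-enhancement
    calculator, and a synthetic-structure generator for fixtures and class
    emulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
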