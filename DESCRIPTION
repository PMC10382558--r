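Package: kirgate
Title: Sub-Conductance Gating Analysis for Kir Potassium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pH-dependent sub-conductance gating in inwardly
    rectifying potassium (Kir2) channels carrying ionizable residues in the
    inner cavity. Implements a non-cooperative per-subunit protonation
    equilibrium model with titration-curve prediction and least-squares
    fitting of the proton dissociation constant and the open/brief-closed
    equilibrium constant; a continuous-time Markov simulator of the gating
    scheme that renders realistic filtered, noisy single-channel current
    traces; all-point-histogram level detection and Viterbi idealization of
    traces into event tables; sub-state statistics (transition matrices,
    time-weighted occupancies, intra-burst closure analysis, dwell-time
    fits, current-voltage conductance fits); and geometric analysis of
    labeled particle trajectories from molecular-dynamics-style data
    (selection cylinders, ion permeation counting, pore occupancy
    histograms, cross-subunit gate diameters), with a synthetic trajectory
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
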