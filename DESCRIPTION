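Package: ionbindr
Title: Transient Ion-Protein Binding, Rotational Relaxation and Solvation
    Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise transient binding of small anions (such as
    superoxide or chloride) to proteins from molecular dynamics trajectories:
    minimum-distance series and binding-event detection, residence-time
    statistics, survival curves with bi-exponential fits, per-residue and
    per-site binding summaries, rigid-body superposition (Kabsch), RMSD/RMSF,
    voxelised ion-occupancy density maps with hotspot extraction, rotational
    correlation times from second-rank orientational autocorrelation, the
    spin-rotational relaxation feasibility arithmetic for radical-pair
    magnetosensitivity, and ion-state-resolved radial distribution functions
    with solvation-shell water counts. Includes synthetic-trajectory
    generators with known ground truth (Markovian site binding, rotational
    Brownian motion, shell-structured pseudo-water) so every analysis stage
    is testable without production MD data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
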