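Package: porepass
Title: Dwell-Time and Occupied-Pore Current Modelling for Solid-State
    Nanopore Miniprotein Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether two similar miniproteins can be distinguished
    by a solid-state silicon nitride nanopore. Converts per-amino-acid
    total-energy-versus-separation scans into pore-wall interaction energies
    (quadratic-spline equilibrium point, Morse-potential asymptote), builds
    protein-level interaction-energy distributions by Monte-Carlo sampling of
    surface-accessibility-weighted contact patches with an exact enumeration
    oracle and gamma fits, and turns those energies into translocation dwell
    times via a Boltzmann transition model whose prefactor is solved from an
    electrostatic-plus-drag equation of motion. Also implements the
    occupied-pore ionic-current analysis chain: displacement-based current
    from ion trajectories, pore-slab ion counting, zero-phase Butterworth
    low-pass filtering, current histograms, center-of-mass tracking and
    dipole-alignment conditioning. Synthetic fixture generators (Morse-shaped
    energy scans, toy proteins, drift-diffusion ion trajectories with known
    expected current) allow the full pipeline to run without molecular
    dynamics or electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    deSolve,
    signal,
    fitdistrplus,
    bio3d,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
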