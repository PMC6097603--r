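Package: rotorwave
Title: Hydrodynamic Synchronization of Driven Colloidal Rotors Above a No-Slip Wall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and analysis of chains of hydrodynamically
    coupled colloidal rotors driven on compliant circular orbits above a plane
    no-slip wall, a minimal model for ciliary metachronal coordination. Provides
    the wall Green's function (Stokeslet plus image system) and mobility
    relations, an adaptive integrator for N-rotor chain dynamics, the averaged
    two-rotor phase theory with its saddle-node synchronization boundary and
    neighbor-coupling fractions, trajectory diagnostics (phase unwrapping, slip
    and wobble detection, Kuramoto-style order parameter of pairwise phase
    differences, end-to-end drift per beat, kymographs), and drivers for
    (height, stiffness) phase-diagram sweeps with optional nearest-neighbor
    truncation of the hydrodynamic coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
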