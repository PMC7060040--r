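Package: sptdomains
Title: Diffusion-State Inference and Membrane Nanodomain Mapping for
    Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Alex", "Moran", email = "alex.moran@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput single-particle tracking
    (spt-PALM) of membrane proteins. Links per-frame localizations into
    trajectories with a density-gated nearest-neighbour rule, infers
    multi-state Brownian diffusion models from large numbers of short
    trajectories two independent ways (cumulative-distribution-function
    fitting of squared displacements, and a hidden Markov model over
    displacements with penalized model-size selection), assigns a diffusion
    state to every step, maps states onto membrane space with auto- and
    cross- pair correlation functions g(r) of averaged state coordinates,
    estimates nanodomain size lower bounds and lifetimes, computes
    deflection-angle distributions, and quantifies non-equilibrium
    steady-state mass flow between states (net flow per state and per arm,
    influx/outflux ratios, stationary distributions, detailed-balance
    residuals). Includes 2D Markov-chain and nested-nanodomain simulators
    with localization error and geometric photobleaching for calibration and
    negative/positive controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
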