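Package: pamsim
Title: Pathway-Activation Modeling of Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the direct axonal response to deep brain stimulation
    (DBS) with patient-style pathway-activation models. Provides an
    equivalent-circuit model of the implanted stimulation system (blocking
    capacitor, lead wires, electrode-tissue interface, parasitics) that
    yields the tissue voltage waveform; analytic and grid-based evaluators
    of the unit static extracellular potential, including diffusion-tensor
    derived anisotropic conductivities; construction of corticofugal axon
    trajectories from tractography-style streamlines with smoothing
    splines, subthalamic collateral branches and double-cable compartment
    placement; an implicit-Euler double-cable myelinated axon simulator
    with fast sodium, persistent sodium and slow potassium nodal channels;
    and threshold search, recruitment, strength-duration and
    charge-duration analyses over bootstrapped fiber populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    splines,
    utils,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
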