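Package: fibrilpulse
Title: Desk-Scale Nonequilibrium Molecular Dynamics of Amyloid Fibril
    Dissociation by Mid-Infrared Electric-Field Pulses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reduced all-site models of capped polyalanine peptides
    assembled into two-layer antiparallel beta-sheet amyloid fibrils in
    explicit three-site water, and simulates their dissociation under a
    train of Gaussian-enveloped mid-infrared electric-field pulses tuned
    to the amide-I (backbone C=O stretch) resonance.  Includes a compact
    molecular-mechanics energy model with a closed-form calibration of
    the C=O stretch stiffness to a target wavenumber, velocity-Verlet
    integration with a Nose-Hoover thermostat, vibrational power spectra
    of the C=O stretch (Welch periodogram), DSSP-criteria secondary
    structure assignment (intermolecular antiparallel beta-sheet and
    helix fractions), oligomer-size distributions by a heavy-atom
    distance cutoff, event-aligned hydrogen-bond break statistics, and a
    scripted-trajectory fixture generator with exact ground truth for
    validating every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph,
    signal,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
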