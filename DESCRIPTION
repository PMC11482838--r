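Package: ringstoich
Title: Rotational Symmetry and Ring Stoichiometry Analysis for Flagellar
    Motor Maps and Tethered-Bead Assays
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the cyclic symmetries and protomer
    stoichiometries of bacterial flagellar motor components. Provides
    cylindrical-coordinate operations on cryo-EM style density volumes
    (lathing, Cn symmetrization, azimuthal power spectra, radial feature
    measurement, low-pass filtering and Fourier shell correlation),
    geometric models of closed protomer rings (arc bending of linear
    oligomers, circumference-ratio stoichiometry prediction and
    symmetry-mismatch registration arithmetic), and recovery of rotational
    dwell positions from tethered-bead x,y trajectories via circular kernel
    density estimation and occupancy-weighted power spectra. A synthetic
    data module generates multi-symmetry motor-like phantom volumes and
    stepping-bead trajectories so that every analysis stage is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'accessors.R'
    'mrc.R'
    'phantom.R'
    'cylindrical.R'
    'spectrum.R'
    'radial.R'
    'filter.R'
    'fsc.R'
    'ring-model.R'
    'bead-sim.R'
    'bead-assay.R'
    'replay.R'
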