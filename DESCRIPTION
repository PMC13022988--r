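Package: transportdyn
Title: Trajectory Analysis of Protonation-Dependent Transporter Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-processing pipeline for molecular dynamics trajectories of
    secondary-transporter systems studied under two protonation conditions.
    Provides Kabsch superposition and RMSD time series with replicate
    aggregation, ligand-residue heavy-atom contact statistics with a
    significant-residue rule, solvent-shell water counting and voxelized
    water-occupancy maps (OpenDX export) with co-localization against
    experimentally modeled waters, time-lagged independent component
    analysis (tICA) with implied timescales, free-energy surfaces in tIC
    space with basin extraction and representative frames, and seeded
    synthetic-trajectory generators (Ornstein-Uhlenbeck, double-well
    Langevin, toy transporter) that supply ground truth for every
    analysis stage at desk scale. Reads PDB, XYZ and DCD trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
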