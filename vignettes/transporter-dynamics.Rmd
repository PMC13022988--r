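---
title: "Characterizing protonation-dependent transporter dynamics from MD trajectories"
author: "transportdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protonation-dependent transporter dynamics from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportdyn)
```

## The analysis problem

Secondary transporters of the LeuT fold couple substrate movement to ion or
proton gradients. In the system this package was built around — an SLC5-fold
histidine transporter fused to a signaling module — the conserved Na2 cation
site is occupied not by a sodium ion but by a lysine side chain whose
protonation state is the experimental perturbation: molecular dynamics (MD)
ensembles are simulated with the lysine protonated and deprotonated (five
independent replicates each, on the microsecond scale), and the analysis asks
how hydration, substrate contacts and slow conformational modes differ
between the two conditions.

`transportdyn` implements that post-processing pipeline as reusable,
tested R functions:

1. **Superposition and RMSD** — Kabsch (SVD) rigid-body fits of every frame
   onto a designated post-equilibration reference, fitting on backbone
   atoms, measuring on separate selections; replicate series aggregated as
   mean ± SEM.
2. **Contact statistics** — ligand–residue minimum heavy-atom distances, a
   contact defined as distance < 3.5 Å, and a *significant residue* rule:
   contact present in at least 10% of frames in either condition.
3. **Hydration** — water counts inside a 1 nm shell around a probe atom,
   steady-state windowing (default: frames after 400 ns), voxelized
   fraction-of-frames occupancy grids exportable as OpenDX, and
   co-localization of experimentally modeled waters with the simulated
   density at the 0.1 occupancy threshold.
4. **Slow modes** — time-lagged independent component analysis (tICA) on
   aligned coordinates, trained on the *combined* conditions so component
   definitions transfer; implied timescales; free-energy surfaces
   F = −kT ln(n/n~max~) over (tIC-1, tIC-2); basin detection and
   representative frames.
5. **Synthetic data** — seeded generators (Ornstein–Uhlenbeck, double-well
   Langevin, a "toy transporter") that emulate the statistical structure of
   the study data so every stage has ground truth at desk scale.

## Data model and conventions

All coordinates are in Ångström and all times in nanoseconds; configuration
values may carry `"nm"`/`"A"` suffixes and are converted on parse. A
`topology` holds atom metadata (name, element, residue, chain) with derived
masks: *heavy* (element ≠ H), *backbone* (names N/CA/C/O outside waters),
*water* (residue names HOH/WAT/TIP3/SOL/TIP). A `trajectory` adds an
`n_frames × n_atoms × 3` coordinate array, the frame interval, a condition
label and a replicate id. Atom indices are 1-based (the R convention);
residue numbers are preserved verbatim from the input PDB, so residues can
be addressed by author numbering (e.g. `resid 196`).

PDB files are parsed by fixed columns; alternate locations keep altloc "A"
or blank and drop the rest with a warning, because the analyses need one
conformer per atom. XYZ trajectories carry no residue metadata, so a
topology from the companion PDB is a required argument. The DCD reader
detects byte order from the leading record marker, rejects fixed-atom
files, and cross-checks the header frame count against the file size. The
saved-frame interval is never inferred from trajectory metadata — it is a
required user input. Readers do no periodic-boundary imaging; trajectories
are expected to contain whole molecules.

## Superposition and RMSD

`kabsch_superpose()` minimizes the RMSD of a selection by SVD of the
cross-covariance of the mean-centered point sets, with the determinant-sign
correction that excludes reflections; it refuses fewer than three or
(nearly) collinear points. `align_trajectory()` fits each frame
independently on the *fit* selection (default: backbone) and applies that
frame's rigid transform to all atoms, so `rmsd_series()` can then measure
any other selection — a ligand, or the flexible helix-break region — in the
frame of the fitted protein without re-fitting. Alignment is idempotent to
numerical precision. Mass-weighting and iterative average-structure
references are deliberately out of scope.

Replicates of unequal length are truncated to the shortest before
aggregation, because the SEM needs the same n at every time point;
`aggregate_replicates()` uses the n−1 sample standard deviation and reports
SEM as missing for a single replicate.

Whether ligand RMSD should use heavy atoms only or all atoms is a judgment
call; the default here is heavy atoms (selections are explicit arguments,
so either is one query away).

## Contacts and the significant-residue rule

Tie-breaking at thresholds is explicit because synthetic tests (unlike real
trajectories) place atoms exactly at boundaries: the contact cutoff is a
strict `<` ("less than 3.5 Å") and the significance threshold an inclusive
`>=` ("at least 10%"). Hydrogens are excluded by element, never by name
prefix. For significance, replicate fractions are pooled frame-weighted —
replicates of different lengths contribute proportionally — with an
`any_replicate` mode provided since the choice between pooled and
per-replicate application of the 10% rule is not dictated by the
definition; pooled is the default. The per-replicate resolution is
preserved in `contact_heatmap_table()` (percentages, residues in
numbering order).

## Hydration

A water molecule is counted once, by its oxygen position; `any_atom` mode
exists for sensitivity checks. Shell membership is strict (`<` radius).
The steady-state window keeps frames with t > 400 ns by default — in the
study system water permeation plateaus around that time — and a start of 0
keeps everything. `detect_plateau_start()` is advisory only (earliest time
from which sliding-window means stay within one SEM of the final-20% mean);
it reports and never overrides the user's window.

Occupancy grids mark, per voxel and frame, whether any counted water atom
falls inside; voxels are half-open intervals so boundary points belong to
exactly one voxel. Replicates are pooled per condition by default
(combining conditions is the caller's choice — pass both lists together).
The voxel edge defaults to 1.0 Å (not a value fixed by the study; it is
configurable), and a 0.1 occupancy isosurface corresponds to water present
in 10% of snapshots. `mask_grid_near()` restricts reporting to within a
radius (e.g. 10 Å of the substrate or the Na2 lysine) after gridding.
`colocalize_waters()` looks up each experimentally modeled water's voxel:
"supported" at or above the threshold, "out_of_region" (flagged, not
scored) outside the grid.

## tICA, free-energy surfaces and basins

For features (flattened aligned coordinates of a selection, d = 3 ×
n~atoms~), the instantaneous covariance C₀ and lagged covariance C~τ~ are
accumulated per trajectory so no lagged pair crosses a trajectory boundary,
all centered on one pooled mean (computed over the head and tail windows
that actually enter pairs). C~τ~ is symmetrized — the standard reversible
estimator for finite sampling — and C₀ is regularized by +εI with ε =
10⁻⁶ · tr(C₀)/d by default. The generalized symmetric eigenproblem
C~τ~ v = λ C₀ v is solved by whitening; eigenpairs are sorted by
descending λ with a deterministic sign convention (largest-magnitude
loading positive), and components are C₀-orthonormal. Implied timescales
follow t = −τ·Δt/ln λ, with λ outside (0, 1) reported as undefined with a
reason code rather than raised. Training one model on the combined
conditions keeps tIC definitions consistent across systems; a
single-condition fit warns. No kinetic-map scaling is applied — the
projections are the bare C₀-orthonormal components. Markov state models,
VAMP scoring and free-energy bootstrapping are out of scope.

Free-energy surfaces are 2D histograms with F = −kT ln(n/n~max~) (kT = 1 so
F is in kT units), empty bins masked rather than zero, and bin edges
computed once from the combined conditions so both surfaces share axes.
`min_count` (default 1) additionally masks bins visited fewer times than
requested: with strongly autocorrelated trajectories, a bin visited once or
twice carries no reliable free-energy estimate, and such bins are vacuous
strict local minima that would be counted as basins. `find_basins()` seeds
a basin at every populated bin strictly lower than all face-adjacent
populated bins, grows it over bins within `depth_cutoff` (default 1 kT,
which separates "stable" from "shallow" basins on the synthetic analogs)
and resolves overlaps by steepest-descent assignment; a flat surface has no
strict minimum and hence no basins. Representative frames are the
projections nearest the minimum-bin center, ties broken by (trajectory,
frame).

## What the synthetic generators emulate — and what they do not

The generators are statistics engines with known ground truth, not physical
models; they exist so that every analysis path can be validated end to end
in minutes on one CPU.

* `gen_ou()` uses the exact OU discretization x~t+1~ = αx~t~ +
  √(1−α²)·σ·ξ, α = exp(−Δt/t~c~), which preserves the stationary variance
  at any step; its lag-τ autocorrelation exp(−τΔt/t~c~) is the analytic
  spectrum tICA must recover.
* `gen_double_well()` integrates overdamped Langevin dynamics in
  U(x) = b(x²−1)² (Euler–Maruyama, with a stability bound on Δt) and emits
  sign(x) as the metastable-state label. Frames are saved every `stride`
  integrator steps (default 20), as MD engines do; this keeps the fast
  intra-well relaxation below one frame so implied timescales are stable
  across lags.
* `gen_toy_transporter()` builds a pseudo-protein whose residues are
  named and numbered after the study system: an upper binding pocket
  (Y51, S53, W55, A56, C74, Y75), a lower exit-channel pocket (F248, S251,
  H257, F406), a flexible three-residue break region, the Na2-site lysine
  K196, one histidine ligand and ideal-gas waters with 3-atom rigid
  geometry (so oxygen-counting conventions are exercised). A telegraph
  process gates the system: while open, the ligand's harmonic anchor moves
  to the lower pocket, the break region shifts and fluctuates more, and
  waters may enter the core; while closed, waters are reflected off an
  exclusion sphere. Every frame receives a random rigid-body rotation and
  translation so alignment is always exercised. Under protonated defaults
  the gate never opens; under deprotonated defaults it opens and closes on
  the 100–500 ns scale.

Default study conditions: 5 replicates per condition, 2000 frames at
0.5 ns/frame (1000 ns, matching the order of the study's 900–1100 ns
replicates at a desk-scale atom count), 200 waters in a 40 × 40 × 60 Å box,
pocket at z = 35 Å and lower site at z = 20 Å, gate rates k~open~ = 0.01/ns
and k~close~ = 0.002/ns when deprotonated (so hydration reaches steady
state within the first half of a replicate and the post-400 ns window is
meaningful), ligand fluctuation 1.0 Å (protonated) vs 1.8 Å (deprotonated),
and a water-exclusion radius of 10 Å matched to the 1 nm probe shell so
closed-gate counts stay several-fold below open-gate counts, as in the
study's 3–5× contrast. These defaults *are* the synthetic study
conditions; tests and the acceptance script run them unchanged.

What the toy system does **not** emulate: force-field energetics,
electrostatics, membrane/lipid environment, barostats, realistic water
structure or residence kinetics, or protonation free energies. Passing
tests therefore demonstrate that the pipeline's statistics are computed
correctly and recover known contrasts — not that the pipeline would reach
the same biological conclusions on any real system.

## Numerical choices

* Whitening-based eigensolver with ridge ε; rank deficiency beyond the
  ridge is an error advising a larger ε, not a silent fix.
* Histogram bin edges get a 10⁻⁹ pad so extreme points stay inside;
  `findInterval(rightmost.closed = TRUE)` handles the top edge.
* The end-to-end condition comparison uses 16 × 16 bins and
  `min_count = 5`: with a ligand correlation time of 25 ns, each 1000 ns
  replicate contributes ≈ 40 independent configurations, so ≈ 200 per
  condition — a 16-bin axis keeps typical populated bins at usable counts
  while still resolving the two pockets, and 5 counts is the smallest bin
  population whose log is worth reading. At this resolution the synthetic
  contrast reproduces the study's qualitative picture: one localized
  protonated basin versus two-to-four spread-out shallow deprotonated
  basins.
* tICA lag for the condition comparison is 200 frames = 100 ns, the lag
  adopted in the study after a 10–200 ns scan; `lag_scan()` reproduces
  such robustness checks.
* Degenerate inputs raise errors naming the offending object (trajectory
  shorter than the lag, empty steady-state window, collinear fit
  selections, ragged tables).

## Problem sizes used in validation

Validation runs are sized for minutes-scale wall time on one CPU: 100
random 10-atom clouds against 10⁴-rotation brute-force sampling for the
superposition oracle; 5 × 10⁵ frames of a mixed 3-D OU process (t~c~ = 50,
10, 2 ns) for analytic tICA recovery; 2 × 10⁵ saved frames of the b = 4 kT
double well for state identification and lag stability; 500-frame random
walks against brute-force voxel assignment; and the full 5 + 5 toy
transporter pipeline (≈ 640 atoms, 2000 frames per replicate) for the
condition contrast.

## Known limitations

* The DCD reader supports the common CHARMM/NAMD layout (optional unit
  cell block, no fixed atoms); exotic variants are rejected rather than
  guessed.
* `significant_residues()` assumes the two conditions share a residue
  universe; comparing different constructs is out of scope.
* Free-energy surfaces are raw Boltzmann inversions of histograms; no
  reweighting, smoothing, or error bars. Basin counts on sparse histograms
  are sensitive to binning — that is inherent to the estimator, and the
  `min_count` mask is the provided control.
* The synthetic water model is an ideal gas with reflection; it validates
  counting and gridding conventions, not hydration thermodynamics.
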