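---
title: "Methods: conformational-dynamics analysis of the SecYEG lateral gate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-dynamics analysis of the SecYEG lateral gate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescope)
```

## Scope and scientific background

The bacterial Sec translocon (SecYEG) conducts nascent polypeptides across,
and releases transmembrane segments into, the inner membrane. Its
bilayer-facing *lateral gate* — the crevice between SecY transmembrane
helices (TMHs) 2b and 7 — opens and closes as substrates engage the
channel. `gatescope` implements the trajectory-analysis layer used to
characterize this kind of conformational dynamics in lipid-embedded
translocons: lateral-gate geometry descriptors, per-residue displacement
fields, all-atom RMSF profiles, Cartesian PCA with Boltzmann-inversion
free-energy landscapes, representative-conformation extraction, and 3D
lipid head-group density grids. It does **not** run molecular dynamics;
trajectories come either from an MD engine (as multi-model PDB or plain XYZ
text) or from the package's own synthetic generators, which provide ground
truth for every analysis stage.

## Data model and formats

Structures are ordered atom lists (serial, name, element, residue
name/id, chain, mass) with Å coordinates; trajectories add an
N × 3 × F coordinate array plus metadata (frame spacing, default 200 ps,
matching the save interval of the microsecond-scale production regime the
generators emulate; replica id). Multi-model PDB is the required trajectory
dialect because it is plain text, diff-able, and needs no binary
dependency; XYZ is a minimal alternative. Author residue numbering is
preserved verbatim — no renumbering — because lateral-gate landmarks are
cited in author numbering. Hydrogens are kept when present; the `heavy`
selection class excludes them, and "all-atom" analyses default to heavy
atoms. When the element column is blank, elements are inferred from the
atom-name justification rules of PDB v3.3; masses come from a fixed
internal element table.

Atom subsets use a small deterministic selection language
(`chain`, `resid a-b`, `name n1,n2`, `backbone` = N/CA/C/O, `calpha`,
`heavy`, combined with `and`/`or`/`not` and parentheses). Resolution is
order-stable, and an empty result is legal — callers decide whether that is
an error.

## Superposition and average reference

Rigid-body fits use the Kabsch algorithm (SVD of the cross-covariance with
a sign correction that enforces det = +1, so reflections are never
returned). Fits are unweighted over the selected atoms, which matches the
common default of MD analysis tools; mass weighting is deliberately not
applied. Collinear fit sets are rejected (second singular value below
1e-10 of the first).

The reference for fluctuation and PCA analyses is the *iterative average
structure*: fit all frames to the current average over the fit selection,
recompute the mean coordinates, and repeat until the mean per-coordinate
change drops below 1e-6 Å (default) or 50 iterations, whichever comes
first (non-convergence returns the last average with a warning). On a
constant trajectory the average equals the frame after one pass.

Displacement fields between two states superpose state B onto state A over
an explicit fit selection and report per-residue Cα vectors and
magnitudes. Correspondence across deposited entries is by (chain,
residue id) after a user-supplied chain map — no sequence alignment is
attempted, which is adequate within one species and keeps the
correspondence auditable. Residues missing on either side are skipped and
listed, not fatal.

## Lateral-gate descriptors

* **Turn COM distances.** Each landmark is the mass-weighted center of
  mass of exactly four consecutive residues (one helical turn); a distance
  series is the per-frame Euclidean distance between two such COMs. Turn
  COMs default to all atoms of the four residues and are configurable to
  backbone or Cα, because deposited models may lack side chains. The
  specific residue quadruplets are configuration inputs, not hard-coded
  constants.
* **Angle η.** The axis of a helix is the vector between the backbone
  (N, CA, C, O) COMs of its first four and last four residues, oriented
  N→C; η is the angle between the axes of TMH 7 and TMH 8, reported in
  [0°, 180°]. On a 20-residue ideal helix this axis estimator carries an
  intrinsic bias below 1° (the 4-residue terminal window spans only 300° of
  the helical wheel, so its COM is slightly off-axis); recovery of
  programmed inter-axis angles is accurate to 1.5° or better, which is the
  tolerance used throughout the tests.
* **Helix/hairpin tilt.** Tilt is the angle between a helix axis (or, for
  an antiparallel hairpin, the normalized difference of the two axes) and
  a membrane normal, folded into [0°, 90°]. A parallel pair passed as a
  hairpin has no defined shared axis and is rejected.
* **Membrane normal.** Deposited models carry no membrane atoms, so the
  normal is estimated from the protein itself as the sign-aligned mean of
  the declared TMH axis vectors. An earlier candidate — the smallest-moment
  principal axis of the bundle's Cα inertia tensor — proved unstable: when
  the bundle's lateral extent rivals the helix length (true at SecY scale),
  the smallest-moment axis flips into the membrane plane. The consensus
  helix axis has no such failure mode and degrades gracefully with bundle
  irregularity.
* **Histograms.** Per-replica relative frequencies over 50 bins spanning
  the pooled min–max range padded by 2% (the binning is exposed; nothing in
  the method fixes it), summarized as the mean and the standard error of
  the mean (sd/√n) per bin over replicas, with the starting-structure value
  reported alongside as the reference line.

## RMSF

Frames are superposed onto the converged average (default), a single-pass
fit to frame 1 (`reference = "first"`), or used as-is
(`reference = "none"`). Per atom, RMSF is the root of the mean squared
deviation from the atom's mean position; residue values are the arithmetic
mean over the residue's analyzed atoms (the maximum is reported alongside
for comparison), and replica pooling returns mean ± SEM per residue.

`reference = "none"` exists because superposing frames that carry *no*
global motion absorbs an O(1/N) share of the fluctuation into the six
rigid-body degrees of freedom — about 2.5% at 40 atoms — which matters when
validating against the isotropic-noise closed form RMSF = σ√3. Real MD
frames always carry global drift, so the default remains the
average-structure fit.

## PCA and the free-energy landscape

Frames of all replicas are pooled, superposed onto the iterative average
over the fit selection (removing global rotation/translation), and the
covariance of the flattened analysis coordinates (atom-major x, y, z) is
eigendecomposed. Analysis coordinates default to Cα atoms, which keeps the
covariance well-conditioned at accessible frame counts; an all-heavy-atom
option exists via the selection. Eigenvalues are non-negative and sorted
descending; each eigenvector's largest-magnitude component is made
positive so projections are reproducible across runs. The spectrum
conserves the total coordinate variance of the superposed analysis atoms.

The configurational free-energy landscape over (PC1, PC2) is a Boltzmann
inversion of the 2D histogram:

ΔG<sub>conf,i</sub> = −RT ln(N<sub>i</sub>/N<sub>max</sub>)

with R = 1.9872036 × 10⁻³ kcal mol⁻¹ K⁻¹ and T = 300 K by default
(configurable). The most populated bin is therefore exactly 0, a bin at
half the maximum population costs RT ln 2 ≈ 0.4132 kcal/mol at 300 K, and
unoccupied bins are *undefined* — carried as +Inf in memory and serialized
as the token `inf`, never as 0 or a large number. Binning defaults to
100 × 100 over the data range padded 2%; absolute ΔG readouts depend on
this choice, which is why landscape values from different binnings are not
comparable and why the package exposes the bins in every interface.

Single conformations are located on a landscape by projection; a
projection outside the edges is flagged and reported with the
nearest bin's value. The representative conformation is the frame whose
(PC1, PC2) lies nearest the center of the most populated bin, with ties
broken toward the lowest (replica, frame) — repeated calls return the
identical frame. Porcupine (PC displacement) vectors scale each atom's
eigenvector segment by scale·√eigenvalue, omitting arrows below a cutoff.

## Lipid density grids

Frames are superposed on the protein frame (fit selection), then particle
positions are binned on a regular grid (default spacing 1 Å; default
extent the fitted protein's bounding box padded 15 Å) and counts are
divided by the number of frames — nothing else. This per-conformation
normalization makes grids from equal frame counts directly comparable and
is exactly invariant under frame replication. Particles outside the extent
are counted and logged, never errors. Grids are exchanged as plain-text
OpenDX scalar fields (z varying fastest), which molecular viewers read
directly. Head-group classes are selection expressions supplied in
configuration; no lipid template library is embedded, because synthetic
particles carry arbitrary names.

## Synthetic generators: what they emulate, and what they do not

The generators produce the regime the analyses were designed for — five
independent replicas, frames every 200 ps, a PC:PG 2:1 particle
composition for lipid fields — with known ground truth:

* `makeIdealHelix`: canonical α-helix backbone (rise 1.5 Å, twist 100°,
  Cα radius 2.3 Å) along an arbitrary axis; the construction oracle for
  every helix-axis operator.
* `makeHarmonicTrajectory`: reference + isotropic per-atom Gaussian noise,
  optionally composed with random global rigid motions; ground truth
  RMSF = σ√3.
* `makeTwoStateTrajectory`: frames drawn from two basins separated along a
  unit collective mode with occupancy p; true labels are returned as a
  side channel, and the basin ΔG difference is −RT ln((1−p)/p). Random
  modes are projected onto the complement of the rigid-body subspace so
  superposition cannot absorb the programmed separation.
* `makeGateToy`: two ideal helices posed per frame so the inter-axis angle
  and the first-turn COM distance follow prescribed schedules exactly.
* `makeLipidField`: uniform slab occupancy plus a programmed Gaussian
  hotspot fraction; classes assigned once per replica at the given ratio.

Reproducibility is bit-exact from (seed, parameters); each replica draws
from its own sub-stream derived from the master seed, so any replica can
be regenerated independently.

What the generators deliberately do **not** model: time-correlated noise
(frames are independent draws, not Ornstein–Uhlenbeck paths — no analysis
in this package depends on autocorrelation), anharmonic basins beyond the
two-state construction, force-field physics, solvent, or membrane
curvature. Passing tests on these fixtures therefore demonstrates the
*estimators* are correct, not that any particular biological conclusion
follows from real trajectories.

## Numerical choices and problem sizes

Tolerances: average-structure convergence 1e-6 Å; orthonormality checks
1e-8; landscape minimum exactly 0 by construction; helix-angle recovery
asserted to 1.5°, turn distances to 0.1 Å. Validation problem sizes were
chosen so each check completes in seconds to a minute on one CPU while
leaving comfortable statistical margin: 5 replicas × 2,000 frames for the
two-state free-energy recovery, 5,000 frames for the RMSF and PCA closed
forms, 10,000 random-rotation trials for the superposition oracle, and
2,000 frames for density hotspot recovery. Degenerate inputs are explicit
errors (collinear fit sets, zero-variance PCA input, parallel pairs
declared as hairpins, non-positive grid spacing) rather than silent
results.

## Known limitations

* Deposited-structure comparisons (e.g. the nanodisc-embedded translocon
  against earlier detergent-state models) require the user to supply the
  coordinate files and the chain map; the package does not download or
  redistribute them, and no sequence alignment backs the residue
  correspondence.
* Helix axes from 4-residue terminal turns carry a sub-degree systematic
  bias on ideal geometry, and more on frayed real helix ends; helices are
  declared, never detected, so the residue ranges are the user's
  responsibility.
* Landscape ΔG values are binning-dependent; only compare landscapes built
  with identical bins, and treat absolute well depths as descriptive, not
  thermodynamic, quantities.
* PDB fixed columns limit coordinates to 0.001 Å and serials to five
  digits (wrapped modulo 100,000 on write).
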