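---
title: "Domain orientation, contacts and clustering: methods and design"
author: "memborient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain orientation, contacts and clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memborient)
```

This vignette is the package's own account of its methods: the models and
conventions behind each observable, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
design choices made where several conventions were defensible.

## The scientific setting

Na~v~ channel β subunits are single-pass membrane proteins: a
transmembrane helix anchors an extracellular immunoglobulin-like (Ig)
domain.  The questions the package's observables address are geometric:
how is the Ig domain oriented relative to the membrane plane, how tilted
is the TM helix, which residues engage lipid headgroups, and how do
multiple copies oligomerize in a crowded membrane.

## Rigid-body orientation

### Model

For the selected atoms (mass $m_i$, position $\mathbf r_i$ relative to
their mass-weighted centroid) each frame's moment-of-inertia tensor is

$$I = \sum_i m_i \left[(\mathbf r_i \cdot \mathbf r_i)\,\mathbf 1 -
\mathbf r_i \otimes \mathbf r_i\right],$$

symmetric positive semi-definite by construction.  Its eigenvectors are
the principal axes; moments are ordered ascending so that $\mathbf p_1$,
the axis of smallest moment, is the domain's *long* axis (for an Ig
β-sandwich, the strand direction).  The rotation carrying the reference
basis onto the body frame is the direction cosine matrix
$R_{jk} = \mathbf e_j \cdot \mathbf p_k$, decomposed as intrinsic-ZYX
Tait–Bryan angles $R = R_z(\mathrm{yaw})\,R_y(\mathrm{pitch})\,
R_x(\mathrm{roll})$ with pitch in $[-90^\circ, 90^\circ]$ and yaw/roll in
$(-180^\circ, 180^\circ]$.  Pitch 0° places the long axis in the membrane
plane; |pitch| = 90° points it along the membrane normal.

### Conventions that matter

* **Selection.**  Orientation should be computed over the domain's stable
  secondary-structure core, supplied as explicit residue ranges; flexible
  loops inflate the apparent motion.  No secondary-structure assignment is
  built in — the annotation is an input, fixed across the trajectory.
* **Eigenvector signs.**  Eigenvectors are defined only up to sign.  The
  first frame fixes signs by alignment with the reference
  ($\mathbf p_k \cdot \mathbf e_k \ge 0$, ties broken toward
  $+\mathbf e_z$); later frames by continuity
  ($\mathbf p_k(t)\cdot\mathbf p_k(t-1) \ge 0$); handedness is restored by
  flipping $\mathbf p_3$.  Without this, pitch series show spurious ±180°
  flips whenever an eigenvector changes sign.
* **Reference modes.**  `standard` measures against the laboratory basis
  (membrane normal = $z$); `firstFrame` measures against the frame-0
  principal axes, so the series starts at (0, 0, 0) and reports motion
  relative to the starting pose.  Both are exposed and neither is
  privileged; when frame 0 happens to be reference-aligned they coincide.
* **Gimbal lock.**  At |pitch| = 90° yaw and roll are not separable; the
  package sets roll to 0, lets yaw absorb the remainder, and flags the
  frame.  Any convention satisfying the composition contract would do;
  pitch, the scientifically interesting angle, is unaffected.
* **Degeneracy.**  Near-equal moments (relative gap below `degenTol`,
  default 1e-6) make axes ill-defined; frames are flagged rather than
  dropped.
* **Sign of pitch.**  Pitch is reported signed by default; histograms can
  fold to |pitch| (`absolute = TRUE`) since some reporting conventions use
  non-negative angles.

### Histograms and pooling

`angleHistogram()` is probability-normalized (bin masses sum to 1) and
pools replicas by weighting every *frame* equally, which is identical to
histogramming the concatenated series — for unequal-length replicas these
two reasonable definitions agree only under frame weighting, which is why
it is the definition used.  `angleHeatmapTable()` resamples mismatched
time grids by nearest frame.

## Helix tilt

Tilt is $\arccos|\hat{\mathbf a}\cdot\hat{\mathbf n}|$, folded to
[0°, 90°] so it is independent of the axis sign, with the membrane normal
fixed to $+z$ (all supported systems are planar bilayer patches; the
vector is configurable, but no local-normal estimation is attempted).

The axis estimator deserves a note.  The obvious choice — the long
principal axis of the backbone point cloud — carries a phase bias for a
discrete single-strand helix: the cross-covariance between the axial
coordinate and the helical phase does not vanish at finite length, and at
TM-helix lengths (36 residues, radius 0.23 nm, rise 0.15 nm/residue) the
bias reaches ~0.4–0.55°.  The package instead averages local axis
vectors built from successive backbone second differences (for four
consecutive atoms the second differences are radial, so their cross
product lies exactly on the local axis) — the construction classical
helix-geometry tools use.  It is exact on ideal helices of any length and
phase; near-degenerate (straight-line) backbones fall back to the
principal-axis estimate.

## RMSD, dihedrals, distances

Kabsch superposition uses the SVD construction restricted to proper
rotations.  RMSD subsets (whole protein / TM residues / extracellular
domain) are ordinary selections; replicate averaging is left explicit to
the caller.  Backbone φ/ψ use the standard atan2 torsion with termini and
missing atoms yielding `NA`, never errors, and the sign convention was
cross-checked against an independent implementation.  Minimum-distance
series support all-pairs (`min`) and COM-to-nearest (`com`) modes, always
minimum-image when a box is present.

## Contacts

Two criteria, both with **strict** `distance < cutoff` comparison
(documented; fixtures avoid exact-boundary values):

* atomistic: sidechain heavy-atom mass-weighted COM within **0.5 nm** of a
  headgroup phosphorus.  Hydrogens are excluded; glycine falls back to Cα
  and is flagged.
* coarse-grained: first sidechain bead within **0.65 nm** of the headgroup
  bead of each lipid type, one series per type.

Occupancy is the fraction of frames in contact; pooling over equal-length
replicas equals the mean of per-replica occupancies.  The reporting mask
keeps residues with occupancy **strictly above 2.5 %** of total time,
pooled across replicas (per-run masks can be built by applying the
threshold per series).  Protein–protein contact probabilities use
any-particle-within-cutoff between copies; the default cutoff reuses the
0.65 nm coarse-grained value — an assumption, exposed as a parameter.
Contact detection is exact: the cell-list accelerated path is
property-tested to agree with an all-pairs brute force on every scene.

## Clustering

Per frame, copies are nodes and an edge joins any two copies with any
particle pair strictly within the cutoff; clusters are single-linkage
connected components.  Single linkage over particle sets (not COM–COM
distance) is deliberate: end-on, fibril-like chains — tip of one Ig domain
against the base of the next — are exactly the case a COM criterion
misses.  Cluster ids are the lowest member index, so outputs are stable
for diffing.  An odd median-smoothing window replaces each frame's edge
set by the majority vote over the window, suppressing single-frame touch
events; the default (window 1) is no smoothing, since the adjacency rule,
cutoff and smoothing are all unreported in typical studies and are
therefore exposed as parameters.

The three-state Ig-pose classification (down / intermediate / up) applies
thresholds to |pitch| with inclusive intermediate bounds; the defaults
(20°, 60°) are package defaults chosen to separate membrane-bound,
transitional and crystal-like poses, not literature values.

## Radial distribution functions

$g(r)$ is the histogram of minimum-image distances from each lipid
reference bead to the protein reference, normalized by shell volume and
mean number density so a uniform species gives 1.  Two reference modes:

* `com`: distances to the protein COM, exact spherical-shell volumes
  $\tfrac43\pi(r_2^3-r_1^3)$ — the mode used for normalization oracles.
* `surface` (default): distances to the *nearest* protein particle.  An
  extended 36-copy protein is not a point, so analytic shell volumes are
  wrong; accessible shell volumes are estimated by seeded Monte-Carlo
  (uniform samples in the box, binned by their own distance-to-protein).
  The seed is recorded in the profile parameters.

Defaults: bin width 0.02 nm, $r_\mathrm{max}$ at most half the smallest
box edge (enforced).  Counts closure — $\sum_r g(r)\,V_\mathrm{shell}(r)\,
\rho$ equals the total counted neighbors — is exact in `com` mode and holds
to Monte-Carlo error in `surface` mode.

## Synthetic scenes: what they emulate, and what they do not

The generators produce the statistical structure the analyses *assume*,
not physical dynamics:

* `makeRigidBody()`: an anisotropic Gaussian cloud (default 500 particles,
  scales 2.0/0.8/0.4 nm, C/N/O masses) expressed exactly in its principal
  frame, rotated per an explicit yaw/pitch/roll schedule, plus isotropic
  per-frame Gaussian noise.  The noise is independent across frames — no
  autocorrelation, no internal flexibility — so recovery tests bound
  estimator error, not sampling error on real data.
* `pitchRampSchedule()` / `stationaryPitchSchedule()`: the ramp covers the
  full pitch range deterministically; the stationary schedule draws i.i.d.
  normal pitches (default mean 30°, sd 1.5°).  The sd default is a
  generator design choice: at 1°-bin resolution and a few thousand frames
  the population mode bin then exceeds its neighbors by ≈5 standard errors,
  so histogram-mode recovery tests are deterministic in practice.  Real
  orientation distributions are broader and autocorrelated; the narrow sd
  tests the histogram machinery, not membrane physics.
* `makeIdealHelix()` / `makeAlphaHelixBackbone()`: Cα traces (rise
  0.15 nm, 100°/residue, radius 0.23 nm; default 36 residues = 10 turns)
  and full N–Cα–C backbones built from canonical internal coordinates
  (φ = −57°, ψ = −47°, ω = 180°).  Tilts outside [0°, 90°] are rejected —
  tilt is sign-free by definition.
* `makeBilayerSurrogate()`: two jittered leaflet lattices of typed
  headgroup markers (P on phospholipids, a choline-like N on POPC, ROH on
  cholesterol, GM on GM3), capacity-checked at 0.6 nm spacing.  It is a
  marker field for contact/distance analyses, not a membrane model: no
  tails, no area-per-lipid physics, no undulations.
* `makeMulticopyScene()`: four-bead rods (distinguishable base/tip, so
  end-on interfaces are testable) shelf-packed so planted chains have
  tip–base gaps at 0.6× the cutoff and distinct clusters are separated by
  more than 2× the cutoff.  In static mode the planted partition is
  guaranteed at every frame; with diffusion it is not (random walks may
  merge clusters).

All generators are deterministic under a fixed seed, restore the caller's
RNG state, and write files the package's own readers accept unchanged.

## Numerical and scope choices

* Units: nm / ps / amu / degrees internally; Å converted once at I/O or
  config parsing (`parseLength("5 A")` → 0.5 nm).  Config cutoffs carry
  explicit units to prevent Å/nm mix-ups.
* Orthorhombic boxes only; triclinic input is an explicit error.  Atom
  indices are 1-based (R convention); residue ids are as in source files.
* File formats: PDB and GRO read/write (GRO parser is in-package; PDB via
  bio3d), multi-model PDB / multi-block GRO / DCD trajectories.  XTC/TRR
  have no R reader available and raise an explicit unsupported-format
  error; the generators emit GRO and multi-model PDB instead.
* Multi-replica input is a list of trajectories over one topology;
  aggregation (histogram pooling, occupancy pooling) is always explicit.
* Desk-scale defaults: ≤ 5,000 particles and ≤ 500 frames per generated
  scene; the test suite's largest cases (a 10⁴-bead ideal-gas RDF over 100
  frames, 5,000-frame orientation series on a 500-particle body) complete
  in seconds to a couple of minutes on one CPU.

## Known limitations

* No triclinic periodicity, velocities, or bonded-topology parsing.
* No local membrane-normal estimation: tilt is measured against a global
  normal, so strongly deformed bilayers would need external preprocessing.
* Contact kinetics (residence times, on/off rates) and depletion/enrichment
  indices are out of scope; occupancy is time-averaged only.
* The synthetic scenes validate estimator correctness, determinism and
  exact recovery of planted structure.  Passing them does not certify
  behavior on real force-field data — flexible domains, correlated noise
  and lipid diffusion are deliberately absent from the generators.
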