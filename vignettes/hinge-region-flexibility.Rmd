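---
title: "Characterizing linker-region flexibility with hingeflex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing linker-region flexibility with hingeflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingeflex)
```

# Scope and model

hingeflex analyzes conformational ensembles of multidomain receptors in
which a flexible linker ("hinge") connects rigid domains — the motivating
case is the thyroid-stimulating-hormone receptor, where a ~130-residue
linker (residues 280–410, containing the proteolytically removed 50-residue
cleavage segment 316–366) joins the leucine-rich ectodomain (22–280) to the
transmembrane bundle (409–694). Those residue ranges are configuration, not
code: every analysis takes selections, and the package has no knowledge of
any particular receptor.

The underlying model is purely geometric. An ensemble is a `Trajectory`:
one `Topology` (atom names, elements, residues, chains) plus per-frame
Cartesian coordinates in Angstrom. No force field, masses or energies are
involved anywhere except the Kabsch–Sander electrostatic hydrogen-bond
model, which is part of the secondary-structure definition itself.

# Analysis criteria and their parameters

**Steric clashes.** A clash is a heavy-atom pair at distance below an
element-dependent threshold: 2.10 Å if either atom is sulfur, 1.68 Å if
either is nitrogen or oxygen, 1.65 Å otherwise. When a pair matches several
classes the larger-element threshold wins (S over N/O over C) — the
thresholds are ordered by element size, so this precedence is the only
self-consistent reading. Summaries count clashing atoms and residues on the
A side only, because the quantity of interest is the clash burden *of the
linker* against a partner. Hydrogens are silently excluded: the criterion
is defined on heavy atoms.

**Mutually-proximal contacts.** Atoms i∈A, j∈B are in contact iff i is the
nearest A-atom to j *and* j is the nearest B-atom to i. This parameter-free
definition adapts to interface curvature where a fixed cutoff would not.
Nearest-neighbor ties (exactly equal distances) break toward the lowest
atom index so that results are deterministic; ties are measure-zero for
real coordinates.

**Hydrogen bonds.** X···H–Y with X, Y polar heavy atoms (N, O, S, P), the
angle at H above 120°, and the X–H distance below a per-acceptor-element
threshold: 2.52 Å (N), 2.52 Å (O), 3.24 Å (P), 3.15 Å (S). Charges are
ignored, so salt bridges are included by construction. Hydrogens are
assigned to their covalent heavy atom geometrically (nearest heavy atom
within 1.2 Å) because multi-model PDB ensembles rarely carry connectivity
records. X and Y within one residue are excluded, matching residue-pair
reporting. Residue-pair *tracks* record per-frame presence; pairs closer
than 5 residues in sequence are dropped (they are dominated by intra-helix
bonds) and pairs bonded in fewer than 15% of frames are dropped. Tracks are
labelled intra-scope versus scope-to-other so linker-internal bonds can be
distinguished from linker–domain anchors. The saturation diagnostic
histograms track first-formation by trajectory quarter; sampling is deemed
saturated when no track first forms in the final quarter.

An open question in the track definition is whether the occupancy filter
applies before or after atom-level bonds are merged into residue pairs.
hingeflex merges first and filters the merged occupancy (the default
reading of a residue-pair plot: a pair is "bonded" in a frame when *any* of
its atom pairs is). The alternative — filter atom-level tracks at 15%, then
merge survivors — is available via `occupancyBeforeMerge = TRUE`; it is
strictly more conservative.

**RMSD maps, clustering, representatives.** `rmsdMap()` samples `nSamples`
evenly spaced frames (index formula `round(1 + i·(F−1)/(n−1))`) and
computes, for each pair, the RMSD over the measured selection after Kabsch
superposition on the fit selection. RMSD is unweighted: "backbone RMSD"
means coordinate RMSD, and no mass weighting is implied anywhere in the
package. Fitting defaults to the measured selection itself (mapping the
linker on itself); passing a rigid domain as `fitSel` instead exposes
relative inter-domain motion. Which convention a published map used is
often unstated; both are first-class here. Note that RMSD after
*independent* superpositions is not a metric — triangle-inequality
violations are possible and are reported as a message, not an error.

k-medoids uses PAM-style alternation (assign to nearest medoid; replace
each medoid by the member minimizing summed within-cluster distance).
Published analyses rarely state initialization or software settings, and
reproducibility demands determinism, so initialization is deterministic:
the first medoid is the global minimax frame, and subsequent medoids are
added by farthest-point seeding; all ties break toward the lowest frame
index. The per-iteration cost is non-increasing, so the alternation
terminates. `k` is a user choice (typically suggested by visual block
structure of the map); the package deliberately has no automatic model
selection. Each cluster is summarized by its *minimax representative* —
the member with the lowest maximum RMSD to the rest of the cluster — which
differs from the medoid (minimum *summed* distance) and is less sensitive
to cluster-size imbalance.

**Helix geometry.** The local axis point of residue i is
`CA_i + r·u_i`, where `u_i` is the unit second difference of consecutive
Cα positions (which points at the local helix axis) and
`r = |Δ²CA| / (2(1 − cos θ))` with θ the turn angle between consecutive
second-difference vectors. The axis direction is the first principal
component of the local axis points, oriented N→C; helix length is the
end-to-end Cα distance. The bend radius is the radius of a least-squares
circle (principal-plane projection, then algebraic fit). The circle is
fitted to the *smoothed local axis points*, not the raw Cα trace: the
helical winding itself (~2.3 Å radius) contaminates a raw-Cα fit, and the
quantity is meant to measure the bend of the helix *path*. Because
published wording ("circle fitted to the Cα atoms") is ambiguous, the raw
variant is available via `bendRadius(ca, useRawCA = TRUE)`. Straight
helices produce collinear axis points; fitted radii above 1000 Å (and
degenerate fits) report the cap value 1000.

Inter-helix metrics: center distance between axis centroids; closest
approach between *finite* axis segments (each spanning its residues'
projections — infinite-line distances can be spuriously small for the
nearly-parallel helices of a transmembrane bundle); unsigned inter-axis
angle in [0°, 180°], with changes reported as simple differences since no
sign convention is defined. Helices containing proline are split into
sub-helices (the proline starts the next segment); segments shorter than 4
residues — the minimum for axis fitting — are discarded with a message, and
split segments are labelled `.1`/`.2`.

The significance flag for bundle-change tables is range-based: a change is
significant (`S`) when the reference value lies outside the range of the
values from the representative structures, with the boundary counting as
inside (`n`). Published table captions sometimes describe the flag with the
opposite wording ("within or outside"); the body-text rule — outside ⇒
significant — is what is implemented, and this discrepancy is deliberately
surfaced here rather than silently resolved.

**Secondary structure.** Classic Kabsch–Sander: backbone hydrogen bond iff
`E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5` kcal/mol (any of
the four distances below 0.5 Å marks a non-bond); n-turns from bonds
CO(i)→NH(i+3/4/5); two consecutive turns make a minimal helix (G/H/I);
parallel/antiparallel bridge patterns make strands, with ladder membership
separating E from isolated B; isolated turns are T; a Cα direction change
above 70° is a bend (S). Code priority is H > E > G > I > B > T > S. Chain
breaks are detected where the peptide C–N distance exceeds 2.5 Å. Amide
hydrogens are reconstructed by default (1.0 Å from N, anti to the
bisector of the C(prev)–N and CA–N bonds) because MD-stripped and synthetic
files often lack them; explicit hydrogens win when present. No single
reference binary is canon for DSSP, so the package promises agreement with
an independent implementation (mdtraj's) of ≥ 95% over its fixture suite on
collapsed H/E/other classes, not per-residue concordance with any one
program version.

**Shape and orientation.** R_g is geometric (unweighted) over the selected
atoms, consistent with unweighted RMSD; a mass-weighted variant exists
behind the `masses` argument. The orientation descriptor is the angle
between the first principal axis of the selection (gyration tensor, i.e.
coordinate covariance — not the inertia tensor, again consistent with the
unweighted choice) and the lab Z axis, the membrane normal in
membrane-protein conventions. Eigenvectors are sign-fixed by continuity
with the previous frame (first frame folded to ≤ 90°) so smoothly rotating
domains do not produce 180° jumps. Heavy atoms are the default selection;
whether hydrogens should enter is unstated in typical published analyses,
so a flag exposes them.

**Two-domain assembly.** With both domains pre-oriented along the membrane
normal, one degree of freedom remains: rotation about Z through the shared
anchor residue's Cα. The scan is 45° coarse over [0°, 360°), then 5° fine
across the winning coarse angle ± 45°, scoring the axis-aligned bounding
box of the merged system ("enclosing rectangle" is read as axis-aligned
because the lab frame is meaningful for pre-oriented inputs; an oriented
bounding box is out of scope, and a mobile-domain-only score is available
behind `mobileOnly`). Each fine candidate carries its mutually-proximal
contacts within a 4.5 Å cutoff — a typical heavy-atom contact distance,
tunable since the original choice of orientation was made by visual
inspection — and the selected orientation maximizes contact breadth
(distinct residue pairs), tie-breaking toward smaller volume then smaller
angle. This selection is an automated, documented stand-in for a visual
choice and is labelled as heuristic in its output. No refinement,
minimization or clash relief follows: that is the job of downstream
simulation.

# The synthetic generators: what they emulate, and what they do not

Every analysis stage is testable without running molecular dynamics because
the generators embed recoverable ground truth:

* `makeIdealHelix()` — Cα atoms exactly on the parametric helix (rise
  1.5 Å, twist 100°, radius 2.3 Å by default: canonical α-helix values).
  With `withBackbone = TRUE`, a full N/CA/C/O (+ amide H) backbone is built
  by internal-coordinate construction at φ = −57°, ψ = −47° with standard
  bond lengths (N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231, N–H 1.0 Å)
  and rigidly superposed onto the parametric trace. Only relative geometry
  matters for the analyses, so these standard constants are not tunable.
* `makeBentHelix()` — the helix wound about a circular arc; the arc radius
  is the ground-truth bend radius, recorded in metadata.
* `makeAntiparallelSheet()` — two extended strands (φ = −139°, ψ = 135°)
  placed antiparallel at hydrogen-bonding offset; a strand-assignment
  fixture.
* `makeRigidRotationTrajectory()` — exact rigid-body rotation schedules:
  internal geometry, distances and R_g are constant by construction, and
  orientation descriptors must read the schedule back.
* `makeCoil()` — a self-avoiding random Cα walk (3.8 Å steps, non-consecutive
  pairs ≥ 4.0 Å), reproducible from its seed: a disorder fixture with no
  backbone, hence no secondary structure.
* `makePairFixture()` — two- to three-atom geometries at exactly requested
  distances/angles for the clash and hydrogen-bond criteria.

What they do **not** emulate: solvent and membrane, sidechains, realistic
Ramachandran variation, correlated domain motions, or force-field energetics.
Passing tests therefore demonstrate that the *computations* are correct and
that ground-truth parameters are recoverable at realistic geometry — not
that any biological conclusion about a particular receptor transfers. The
real-data checks (cysteine SG–SG distances in the deposited initial TSHR
model; clash counts against LRD-superposed antibody structures) require
downloads and report a clear failure when those files are absent; the clash
counts are additionally sensitive to the superposition used, which is why
they are kept separate from the desk-scale suite.

# Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with a determinant correction, so
  reflections are never returned; near-collinear point sets are flagged.
* Circle fits cap at 1000 Å: beyond that, curvature is not distinguishable
  from straightness at protein scale.
* Empty selections are errors for analyses but only warnings at selection
  time, so configs can be validated before running.
* Segment–segment closest approach uses the clamped closest-point
  parametrization; parallel segments fall back to the standard special case.
* The k-medoid `seed` argument exists for interface stability; the
  procedure is deterministic and ignores it.
* `readPDB()` validates per-model atom counts before parsing and treats a
  file without MODEL records as a single frame. Coordinates are written at
  the PDB's 3-decimal precision, the round-trip tolerance.
* Element inference: explicit element column > two-letter symbol match
  (only outside standard residues, so `CA` stays an α-carbon) > first
  alphabetic character; unresolvable names become `"other"` with a warning.

# Problem sizes in the shipped tests

The test suite and acceptance script run on deliberately small problems:
ensembles of 6–12 frames and 10–80 atoms, 100 randomized instances of ≤ 60
atoms for the brute-force pair-finder comparisons (plus one 500-atom
instance), 10×10 matrices for the representative oracle, 30-residue helices
for bend-radius recovery, and a 5-fixture suite (~70 residues) for the
reference-DSSP comparison. These sizes give sub-second individual checks
while exercising every code path; all analyses scale to the 2000-frame maps
typical of production trajectories, since the map is the only O(n²) stage.

# Known limitations

* PDB is the only structure dialect (no mmCIF, no binary trajectory
  formats); the `Trajectory` contract isolates readers, so adapters can be
  added without touching analyses.
* Kabsch–Sander here implements the classic rules; π-helix refinements and
  polyproline-II detection of newer DSSP variants are out of scope.
* The assembly heuristic assumes pre-oriented inputs and a single rotational
  degree of freedom; it is not a docking method.
* The contact-breadth orientation selection formalizes a judgment call;
  different cutoffs can prefer different orientations, which is why the
  cutoff is a parameter and the scan report retains all candidates.
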