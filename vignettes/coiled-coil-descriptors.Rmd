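---
title: "Geometric descriptors of coiled-coil receptor activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric descriptors of coiled-coil receptor activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccgeom)
```

## The scientific problem

Transmembrane sensor histidine kinases such as the nitrate/nitrite sensor
NarQ transmit a periplasmic binding event across the membrane through a
four-helix coiled coil.  Each protomer of the homodimer contributes an
ascending arm (transmembrane helix TM1 continuing into sensor helix H1)
and a descending arm (sensor helix H4 continuing into TM2).  Three
candidate rigid-body motions of this bundle have been proposed as the
signal carrier, and they are not mutually exclusive — they are simply
different degrees of freedom of a coiled coil:

* **helical rotation** — a helix turns about its own axis, visible as a
  uniform shift of its per-residue Crick angles;
* **diagonal scissoring** — like helices of the two protomers move apart
  while the other pair moves together, visible in cross-protomer
  C$\alpha$ distance profiles;
* **piston** — one helix slides along the membrane normal relative to its
  partner, visible as a difference of axial center-of-mass projections.

Two secondary-structure observables couple to these motions: the
$\varphi/\psi$ state of the five-residue sensor–TM linker (helical or
disordered), and the backbone hydrogen-bonding class of the
ligand-contacting glycine (an $\alpha$-helical $i \to i{+}4$ bond versus
the tighter $3_{10}$-like $i \to i{+}3$ bond).

`ccgeom` computes all of these descriptors on static dimer structures and
over trajectory windows, and provides a synthetic dimer generator whose
imposed motions serve as exact ground truth for recovery tests.

## Local helix axes and Crick angles

For residue $i$ of a helical C$\alpha$ trace the second difference
$\Delta_i = \mathrm{CA}_{i-1} + \mathrm{CA}_{i+1} - 2\,\mathrm{CA}_i$
points radially from the C$\alpha$ toward the local helix axis; for an
ideal helix of radius $r$ and twist $\tau$ its magnitude is exactly
$2 r (1 - \cos\tau)$.  `fitLocalAxis()` therefore estimates the local
twist from the angle between $\Delta_i$ and $\Delta_{i+1}$ (a four-residue
window, $i{-}1 \dots i{+}2$), the radius from the radial magnitude, and
places the axis point at $\mathrm{CA}_i + r\,\hat\Delta_i$.  On ideal
helices the construction is exact; under coordinate noise its error grows
smoothly (the tests check monotone degradation over
$\sigma \in \{0, 0.1, 0.3, 0.5\}$ Å with fixed seeds).  Tangents are
central differences of axis points, oriented N→C, and terminal residues
carry no axis point.

The **Crick angle** of a residue is measured in the plane perpendicular
to its local tangent, from the projection of the vector axis-point →
nearest-point-on-the-bundle-axis to the projection of the vector
axis-point → C$\alpha$.  Zero means "this residue faces the bundle
core"; the sign is right-handed about the N→C tangent (one exported
constant, `ccgeomCrickSign`, documents and controls the convention).
Successive residues of an ideal $\alpha$-helix (3.6 residues/turn) step
by $100°$; rotating a helix about its own axis by $\delta$ shifts every
Crick angle by $\delta$, which is how `compareTwoStates()` and the
recovery tests read out helical rotation.  All aggregation over frames
uses circular statistics (`circularMean()`, `circularSD()`); linear means
of angles are deliberately not offered, because distributions near the
$\pm 180°$ wrap would otherwise produce $360°$ artefacts.

The **bundle axis** is the first principal component of the pooled axis
points of the core helices, oriented N→C along the first supplied axis.
Callers pass the H1 arm of protomer A first, so the direction runs from
the cytoplasmic (TM) end toward the periplasmic (sensor) end; this single
convention fixes every axial sign in the package (piston positive toward
the periplasm).  Pooled-PCA needs the helices to be longer than their
lateral separation — for very short segments the first component can flip
into the separation direction, so the pipeline pools the full H1 and H4
segments of both protomers.  A membrane normal, when known, can be passed
anywhere an `AxisLine` is accepted; synthetic fixtures have no membrane,
so the bundle axis stands in for it.

## Distances, piston, linker state, hydrogen bonds

All distance descriptors use C$\alpha$ atoms only, with equal weights:
the intra-protomer 50–133 contact (the backbone-level readout of the
arginine/serine–aspartate coupling in the ligand pocket), the
cross-protomer same-residue profiles over residues 34–50 (TM1/H1 side)
and 133–147 (H4/TM2 side), and the piston shift — the difference of the
C$\alpha$ center-of-mass projections of TM1 and TM2 on the reference
axis.  Superpositions (`kabschSuperpose()`) are least-squares rigid
fits over C$\alpha$ atoms computed by singular value decomposition with
the proper-rotation correction; the reported RMSD always equals the
brute-force RMSD after applying the returned transform.

$\varphi/\psi$ dihedrals follow the standard definitions and are flagged
undefined at chain termini or where backbone atoms are missing (missing
atoms are never fabricated).  `classifyAlpha()` calls a residue helical
iff $\varphi \in [-120°, -30°]$ and $\psi \in [-80°, -5°]$ (closed
intervals, boundaries count as helical; the window is configurable).
This window is a package default for the $\alpha$ region, not a claim
about any published cutoff — the generator-built test cases are
unambiguous under any reasonable window.  A linker (residues 34–38) is
called *broken* if any residue is disordered and *helical* if all
classifiable residues are helical.

Backbone hydrogen bonds at an acceptor residue $i$ are tested for the
two donors $i{+}3$ ($3_{10}$-like) and $i{+}4$ ($\alpha$); both may
coexist (bifurcated).  The criterion is
$d(\mathrm{O} \cdots \mathrm{N}) \le 3.5$ Å **and**
$\angle(\mathrm{C{=}O} \cdots \mathrm{N}) \ge 120°$.  The directionality
term is not optional: on an ideal $\alpha$-helix the $i{+}3$ O···N
distance is $\approx 3.2$ Å — inside any defensible distance cutoff — so
a distance-only rule can never separate the two helix classes.  The
carbonyl angle does separate them cleanly: $\approx 111\text{–}117°$ for
the spurious $\alpha$-helix $i{+}3$ contact versus $\gtrsim 140°$ for
genuine bonds.  Amide hydrogens are not present in backbone-only models,
which is why the angle is measured at the carbonyl rather than at the
donor.  Both thresholds are configurable.

## The synthetic dimer generator

`buildDimer()` constructs a C2-symmetric four-helix dimer: protomer A is
assembled from two ideal-helix arms (TM1+linker+H1 ascending, H4+TM2
descending, axes 12 Å apart at 90° around the bundle axis), the state
parameters are applied as rigid sub-transformations, and protomer B is
the exact C2 image of the finished protomer A.  The imposed parameters —
recorded in the model's provenance as ground truth — are:

* `h1RotationDeg`: rotation of H1 (residues 39–60) about its own axis;
* `pistonTm1Z`, `pistonH1Z`: axial offsets of TM1 and H1 (pure z
  translations, so piston recovery is exact by construction);
* `scissorH1Tip`, `scissorH4Tip`: changes of the cross-protomer distance
  at the membrane-proximal endpoint residues (34 and 147), realised as
  calibrated rigid tilts of whole arms about their membrane-distal ends
  (the tilt angle is solved numerically so the endpoint change is exact);
* `linkerState`: helical, or broken by rebuilding residues 35–38 (and
  $\psi_{34}$) with $\varphi/\psi = (-80°, 60°)$ while TM1 and H1 stay
  on their cylinders;
* `d50_133`: the 50–133 contact distance, set exactly by a horizontal
  shift of the H4+TM2 arm solved jointly with the H4 scissor tilt;
* `sigma`, `seed`: i.i.d. Gaussian coordinate noise, seeded.

`makeTrajectory()` strings two such states into a seeded pseudo-trajectory
(bound frames before the switch fraction, free frames after, fresh noise
per frame); identical seeds give bit-identical coordinates.  The
*bound-like* preset is the reference state with a broken linker and the
contact at 7.1 Å; the *free-like* preset encodes the activation
mechanism's directions relative to it — H1 rotated 26°, H1–H1′ tips 2 Å
closer, H4–H4′ tips 2 Å apart, TM1 offset 3 Å and H1 offset 1 Å (the
linker-break amplification of the piston), continuous linker, contact at
7.9 Å.  The magnitudes are test parameters chosen inside physically
reported ranges, not claims.

Several construction choices deserve a note:

* **Over-determined helix parameters.**  A helix spec names rise, twist,
  radius *and* $\varphi/\psi$; with standard peptide bond angles,
  $(-57°, -47°)$ implies twist $99.4°$, rise $1.556$ Å, radius
  $2.278$ Å — not the requested $(100°, 1.5, 2.3)$.  `buildIdealHelix()`
  honours every user-visible parameter exactly by relaxing the three
  internal backbone bond angles within a penalty around standard values;
  the dihedrals and the C$\alpha$ cylinder are then both exact.  If a
  request is too strained to reconcile (e.g. $\alpha$ dihedrals forced
  onto a $3_{10}$ cylinder) the builder warns and comes as close as it
  can.
* **Pseudo-conformers, not physics.**  The rigid sub-transformations
  deliberately break covalent continuity at segment boundaries (for
  example the C(38)–N(39) peptide bond in the broken-linker state, or
  the linker stretch under a TM1 piston).  The generator produces
  geometric ground truth for descriptor recovery, not physically
  realisable conformers, and no solvent, membrane or ligand atoms.
* **Rotation couples to CA-based profiles.**  Rotating a helix of
  C$\alpha$ radius $r$ about its own axis moves each C$\alpha$
  azimuthally, changing its distance from the bundle axis by up to
  $2 r \sin(\delta/2)$ — about $1$ Å per protomer at $\delta = 26°$.
  Same-residue cross-protomer distances at rotated residues therefore
  change by up to $\sim 2$ Å under a pure rotation; only residues outside
  the rotated range are invariant.  This is a geometric fact about
  CA-based profiles, not an artefact.
* **The contact constraint couples H1 motions to the H4 arm.**  Because
  the generator holds `d50_133` exactly, transforms that move CA(50)
  (rotation, H1 piston, H1 tilt) drag the H4+TM2 arm slightly.  The
  scissor-tip targets are anchored to the zero-scissor placement under
  the same contact constraint, so builds differing only in scissor
  parameters show exactly the imposed tip changes.
* **Bundle packing.**  The default 12 Å separation keeps every preset
  state, including a 90° H1 rotation, clear of the generator's 2.0 Å
  inter-chain clash threshold (checked on the clean construction,
  before noise).

## The trajectory pipeline

`runDescriptors()` evaluates the configured battery per frame and per
protomer, flags isolated failures as missing (counting them), and aborts
only when a descriptor fails on more than half of the frames.
`windowLast()` keeps the frames with time strictly greater than
$t_\mathrm{end} - T$ (a window equal to the full span keeps everything);
with the canonical 200 ns window on a 10 ns grid this yields exactly 20
frames.  `exportSnapshots()` picks the frame nearest each stride point
(each frame used at most once, so incommensurate grids degrade
gracefully) and superposes every snapshot on the first over the C$\alpha$
atoms of residues 45–55 of both protomers.  `overlayReference()`
evaluates each scalar descriptor once per labelled reference structure —
reference values are always computed, never hard-coded.
`compareTwoStates()` superposes two conformers on the core set (residues
48–54 and 122–130, both protomers), then reports per-residue Crick
changes over the membrane-proximal H1 range (43–55), cross-protomer
profile changes, the linker call per structure, and per-residue axial
displacements of TM1 measured after superposition on TM2 (and H1 on H4)
— the operational definition of "piston of one segment relative to its
partner".  Swapping the two structures flips the sign of every
displacement field exactly.  The whole pipeline is deterministic:
identical inputs and seeds give bit-identical CSV outputs.

`protomerAsymmetry()` — the C$\alpha$ RMSD between the two protomers of
one model after optimal superposition — is provided as a simple internal
symmetry summary.  It is a plain geometric heuristic, not a published
asymmetry estimator.

## What the tests do and do not show

All recovery tests run on generator ground truth: at $\sigma = 0$ the
pipeline recovers imposed rotations within 2°, pistons within 0.05 Å,
scissor tips within 0.1 Å and linker states exactly, and at
$\sigma = 0.3$ Å rotations within 5°.  The problem sizes are desk-scale
by design: dimers of 190 residues, trajectories of 20–200 frames, and a
101-frame, 1000 ns fixture for the window arithmetic; the full suite runs
in well under a minute.  Passing them shows that the descriptor
definitions and their implementation are correct and mutually consistent
— it does not validate force fields, sampling, or any physical claim
about real receptor dynamics.  The generator emulates geometry (two
states, C2 symmetry, isotropic Gaussian noise); real molecular-dynamics
data have correlated anisotropic fluctuations, bending and fraying
helices, a membrane, and asymmetric protomers, none of which the
synthetic fixtures reproduce.

## Known limitations

* Backbone-only: side chains are ignored everywhere; the 50–133 salt
  bridge is tracked through its C$\alpha$ proxy distance.
* Multi-model PDB is the only trajectory dialect read; binary formats
  (XTC/DCD) are out of scope here.
* Residue numbering is author numbering throughout and is never
  re-indexed; segment definitions assume it.
* The H-bond criterion is geometric (distance + carbonyl angle), with no
  energy term; bifurcated bonds are reported, not resolved.
* The bundle axis from pooled helix axes requires helices longer than
  their lateral separation; for stubby segments supply an explicit axis.
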