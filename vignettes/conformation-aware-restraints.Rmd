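---
title: "Conformation-aware torsion restraints and ring-pucker validation for pyranoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformation-aware torsion restraints and ring-pucker validation for pyranoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarpucker)
```

## The problem

Pyranoses — monosaccharides forming a six-membered, five-carbon/one-oxygen
ring — are overwhelmingly found in their lowest-energy chair conformation:
^4^C~1~ for D-sugars and ^1^C~4~ for L-sugars. Non-chair conformations
(boats, skew-boats, envelopes, half-chairs) cost substantial energy and in
folded structures normally appear only as catalytic intermediates, so a
modelled high-energy ring is either a genuine, density-supported
observation or a refinement artefact. At the resolutions typical of
glycosylated structures, refinement needs prior stereochemical knowledge —
restraint dictionaries — to keep sugar geometry sensible, and classic
dictionaries restrained ring torsions only loosely (uniform 20 degree
sigmas, 2/3/6-fold periodic targets), which lets a ring sink into weak
density in a distorted conformation.

This package implements and tests the remedy: *conformation-aware,
unimodal ring torsion restraints*. The six endocyclic torsions of a
monomer are measured from a low-energy conformer's Cartesian coordinates
and written into the dictionary as `ring_1`..`ring_6` with a single target
per 360 degrees (period 1) and a tight sigma, separated from all remaining
torsions (`tors_*`), which keep a looser sigma. A generic 60 degree target
is deliberately *not* used: the endocyclic oxygen makes the ring bond
lengths unequal, so the true chair torsions deviate from 60 (about 53.65
degrees along O5–C1–C2–C3 for a low-energy GlcNAc conformer).

## Cremer–Pople puckering and conformer naming

Ring conformation is quantified with Cremer–Pople (CP) coordinates. For
six atoms the out-of-plane displacements `z_j` relative to the CP mean
plane reduce to three degrees of freedom: an amplitude/phase pair
`(q2, phi)` from the second-order Fourier sums and a signed alternating
amplitude `q3`, combined into spherical coordinates

* `Q = sqrt(q2^2 + q3^2)` — total pucker amplitude (Å),
* `theta = atan2(q2, q3)` in [0, 180] — pole-to-pole conformation angle,
* `phi` in [0, 360) — pseudorotation phase.

Conventions in this package (they matter and are tested):

* atom index `j = 0` is the ring oxygen, and the traversal runs through
  the anomeric carbon (`O5 -> C1 -> C2 ...` for aldopyranoses). With this
  choice `theta = 0` is the ^4^C~1~ chair of a D-aldopyranose and
  `theta = 180` is ^1^C~4~.
* `phi = 0` is the O,3B boat (ring oxygen and C3 above the plane);
  boats sit at multiples of 60 degrees and skew-boats at odd multiples of
  30. This fixes boat/skew naming such as 1S5 (phi = 270) and 2SO
  (phi = 150).
* the classifier's canonical table places envelopes at
  `theta = 54.74` / `125.26` (phi = 60k) and half-chairs at
  `theta = 50.77` / `129.23` (phi = 60k + 30). These are the *exact* CP
  positions of the ideal one-atom-out (envelope) and
  two-adjacent-atoms-out (half-chair) displacement patterns under the CP
  mode decomposition, derived from the Fourier projections; prose
  descriptions sometimes round the tropics to "~45 and ~135 degrees", and
  a simplified table would put both families on one tropic. We use the
  exact positions so that ideal envelope/half-chair geometries classify to
  themselves. There are 38 canonical conformers in total (2 chairs, 6
  boats, 6 skew-boats, 12 envelopes, 12 half-chairs).

`classify_conformer()` assigns the nearest canonical conformer by
spherical arc distance, with ties broken towards the lower-energy family
(chair, then boat/skew-boat, then envelope/half-chair) and then
lexicographically. Rings with `Q < 0.1` Å are reported as planar rather
than classified: below that amplitude `theta`/`phi` are numerically
meaningless for real coordinates.

`build_ring()` is the inverse transform (hexagon plus CP displacement
field); the forward/inverse round trip recovers `(Q, theta, phi)` to
better than 1e-6 over a full grid of the sphere, which is tested.

## Dictionary patching

`patch_dictionary()` takes a monomer-library restraint dictionary and its
low-energy conformer coordinates and

1. emits the six endocyclic torsions as `ring_1..ring_6`, period 1
   (unimodal), sigma `sigma_ring` (default 3.0 degrees), each with the
   target *measured* from the conformer. `ring_k` is the torsion about the
   bond between ring positions `k` and `k+1` starting at the
   oxygen–anomeric bond, so `ring_2` of an aldopyranose is O5–C1–C2–C3.
   Period 1 is the monomer-library mechanism for a unimodal restraint.
2. renames every other heavy-atom torsion `tors_<k>`, re-measures its
   target when all four atoms are present in the conformer, and assigns
   sigma `sigma_other` (default 10.0 degrees) unless the input sigma was
   already tighter. Torsions involving hydrogens are dropped.
3. passes bonds, angles, chiralities, planes and the component type
   (`pyranose` / `ketopyranose`, needed for glycosidic-link restraints)
   through untouched.

Patching is idempotent, and the CIF writer emits ring torsions first with
fixed 3-decimal formatting so a write–read–write cycle is byte-identical.
The sigma defaults are exposed as knobs (`sigma_ring`, `sigma_other`); the
3.0 default is the tightest of the commonly explored grid (3.0, 6.0,
10.0), the value that suppresses conformational outliers without
distorting agreement with the data.

The ring is found by graph search on the bond list (the unique six-cycle
with one oxygen and five carbons), not by atom names, so remediated or
legacy naming and ketopyranoses all work. The anomeric carbon is the ring
carbon with the most exocyclic oxygens (tie: lowest-numbered name), which
reduces to C1 for aldopyranoses and C2 for ketopyranoses.

## Validation: the yes / check / no diagnosis

`diagnose()` evaluates four criteria per sugar:

1. **anomeric configuration** — the axial/equatorial disposition of the
   anomeric substituent, computed from the angle between the
   anomeric-carbon-to-substituent vector and the CP mean-plane normal,
   against the disposition implied by the component's series and declared
   anomer in the observed hemisphere (alpha is axial in the home chair for
   both series). Near the equator (theta within 15 degrees of 90) or with
   the substituent absent (e.g. glycosidic link not included) the check is
   indeterminate and passes with a warning detail.
2. **chirality** — the sign of the scalar triple product at each chiral
   restraint centre must match the dictionary sign.
3. **puckering amplitude** — `Q` within [0.35, 0.9] Å by default,
   bracketing typical chair amplitudes (~0.55–0.63 Å); configurable, as
   no universal printed threshold exists.
4. **ring conformation** — the classified conformer must equal the
   expected lowest-energy conformer (a named-label comparison, not a raw
   theta proximity).

The verdict is `yes` when all four pass, `check` when the conformation is
the *only* failure (a high-energy pucker the user should inspect against
density), and `no` otherwise. The built-in expectation table covers NAG,
MAN, BMA, GLC, BGC, BOG, FUL, GAL, GLA and SIA, with the D-series
defaulting to 4C1 and L-series to 1C4 and per-component overrides
possible. `batch_report()` aggregates verdicts, optionally in three
equal-count resolution bins.

## Density and RSCC

`calc_density()` renders a model as a sum of unit-peak isotropic Gaussians
on a grid, and `rscc()` computes the Pearson correlation between two grids
over voxels within `mask_radius` (default 2.5 Å) of the model's atoms.
This is a synthetic stand-in for a crystallographic 2mFo−DFc map — there
is no structure-factor calculation — so RSCC numbers are comparable only
within this package; the *qualitative* behaviour is what is reproduced
and tested: density generated from a boat conformer correlates better
with the boat model than with the chair model, so restraining a sugar to
its likely chair can cost a little RSCC. Minimal CCP4/MRC (mode 2) map
I/O is provided for interoperability.

## The toy regularizer

`regularize()` is a deliberately small quasi-Newton (BFGS with Armijo
backtracking, energy tolerance 1e-8) minimizer of
`sum(((measured - target)/sigma)^2)` over bond/angle/torsion restraints,
optionally minus `weight` times the trilinearly interpolated density at
the atom positions. It is **not** a crystallographic refinement engine; it
exists to make the central behavioural claims observable at desk scale:

* boat-started rings with sigma-3 unimodal ring torsions return to the
  chair (the tested ensemble uses 50 random boat phases with 0.02 Å
  coordinate noise, seed 4117; at least 95% must finish within 10 degrees
  of the pole, and in practice all do);
* with bond/angle restraints only, the boat survives (bonds and angles are
  satisfied by boats too — this is exactly why ring conformation is a
  useful validation metric);
* legacy-style 20-degree-sigma torsions with 2/3/6-fold periods are
  nearly inert: the boat's torsions sit close to symmetry-equivalent
  targets, so the multimodal restraints cannot restore the chair;
* a strongly weighted density term made from a boat conformer holds the
  boat against the chair-pulling torsions, mirroring how refinement
  down-weights restraints against strong observations.

One numerical point deserves emphasis. In the strong-data demonstration
the "observed" map must be *featureful*: we use Gaussian width 0.45 Å on
a 0.25 Å grid. With a broad (0.9 Å) map the blobs of neighbouring atoms
merge and the density carries no conformational signal at all — a
minimizer can then harvest more density by compacting the molecule into
the merged blob than the honest boat pose collects, which is an artefact
of the sum-of-Gaussians data term, not a refinement behaviour. A sharp
map is the desk-scale analogue of the "strong and featureful" density
that justifies keeping a high-energy conformer. The demonstration weight
(1e4) makes the data term dominate the torsion penalty by roughly an
order of magnitude at the boat.

Trilinear interpolation makes the density gradient piecewise-constant per
voxel; that is smooth enough for the backtracking line search, and all
restraint gradients are analytic and verified against central finite
differences to 1e-4.

## The synthetic generator, and what passing tests do not show

`make_sugar()` builds idealized aldopyranoses: ring from the inverse CP
transform at the conformer's canonical pucker (Q = 0.55 Å, hexagon radius
1.45 Å), substituents (O1–O4, C6, O6) on exact tetrahedral directions
(1.43 Å C–O, 1.52 Å C–C), axial/equatorial placement per the component's
stereo configuration (gluco, manno, galacto patterns) and anomer;
L-sugars are mirror images of the D construction, which turns 4C1 into
1C4 and inverts every centre consistently. Non-chair targets are reached
by `distort_ring()`, which interpolates the CP displacement field while
carrying each substituent rigidly on its ring atom's local frame, so
configuration is preserved exactly. Dictionaries carry measured bonds and
angles, chirality signs computed from the built coordinates, and generic
AceDRG-style torsions (ring torsions at the generic 60 degrees, sigma 10,
period 3) ready to be patched.

The generator emulates the *logic* of real dictionary generation, not its
numbers: no database-derived bond/angle targets, no hydrogens, no
B-factors, no solvent, simplified substituents (NAG is modelled with O2
rather than the N-acetyl arm). Tests passing on these fixtures establish
the correctness of the measurement, patching, classification, diagnosis
and minimization machinery — they do not certify behaviour on real
crystallographic data, which additionally involves map noise, partial
occupancy, and linkage context.

## Problem sizes and numerical choices

The test suite runs the classifier against a brute-force nearest-neighbour
oracle on 10,000 uniformly distributed sphere points, the forward/inverse
CP round trip on a 13 x 24 x 3 grid at 1e-6 tolerance, and the
three-protocol regularizer ensemble on 50 seeded boat starts (around 80 s
in total). The bare six-atom ring is used for the ensemble: it isolates
the restraint landscape from substituent effects and keeps the experiment
fast; the full-sugar behaviour is covered by single-run tests. Degenerate
inputs are handled explicitly: planar rings get a planar pseudo-label,
collinear torsions raise a named error inside `dihedral_angle` but are
skipped with a warning inside the energy function, and sub-threshold
puckers never reach the classifier.

## Known limitations

* The anomeric check is geometric (normal-angle rule) and declares
  equatorial-band conformations indeterminate; full CIP assignment is out
  of scope.
* RSCC values are internally consistent only; no structure factors.
* The regularizer has no nonbonded terms, so nothing except bonds/angles
  prevents self-overlap under extreme data weights.
* Ketopyranoses are supported in ring detection, measurement and
  patching; the synthetic generator builds aldopyranoses only.
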