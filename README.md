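# sugarpucker

Conformation-aware restraint dictionaries and ring-pucker validation for
pyranose sugars, in R.

## What problem this solves

Pyranoses (six-membered sugar rings: five carbons, one oxygen) sit almost
always in their lowest-energy chair — ⁴C₁ for D-sugars, ¹C₄ for L-sugars.
Classic refinement dictionaries restrained their ring torsions with
multimodal targets (periodicity 2/3/6) and a uniform 20° uncertainty, which
cannot hold a chair: during refinement against weak density a sugar can
slide into a boat or skew-boat with near-ideal bonds and angles. This
package is for structural biologists and methods developers who work with
carbohydrate models and restraint dictionaries: it patches
monomer-library-style CIF entries with *unimodal* ring torsion restraints
measured from a low-energy conformer, validates sugar models via
Cremer–Pople puckering, and demonstrates the refinement consequences with
a desk-scale restrained regularizer.

## The method

For ring atoms ordered oxygen-first through the anomeric carbon, the
Cremer–Pople transform maps the out-of-plane displacements `z_j` to

    q2·cos φ = √(1/3) Σ z_j cos(4πj/6)        q3 = √(1/6) Σ (−1)^j z_j
    q2·sin φ = −√(1/3) Σ z_j sin(4πj/6)
    Q = √(q2² + q3²),  θ = atan2(q2, q3) ∈ [0°, 180°]

so θ ≃ 0° is ⁴C₁, θ ≃ 180° is ¹C₄, and the θ = 90° equator holds boats and
skew-boats. Conformers are classified to the nearest of the 38 canonical
(θ, φ) points. Dictionary patching emits the six endocyclic torsions as
`ring_1..ring_6` — period 1 (one target per 360°, i.e. unimodal), σ = 3.0°,
values measured from the conformer's Cartesian coordinates rather than a
generic 60° — and renames all other torsions `tors_*` with σ = 10.0°. A
per-sugar diagnosis checks anomeric configuration, chirality, puckering
amplitude Q and ring conformation: all pass → `yes`; conformation the sole
failure → `check` (inspect against density); anything else → `no`.

## Worked example

```r
library(sugarpucker)

fx <- make_sugar("D", "4C1", "beta", "NAG")     # synthetic sugar + dictionary
p  <- patch_dictionary(fx$dictionary, fx$coords)
p$torsions[1:6, c("id", "atom1", "atom2", "atom3", "atom4", "value", "sigma", "period")]
#>       id atom1 atom2 atom3 atom4     value sigma period
#> 1 ring_1    C5    O5    C1    C2 -54.26245     3      1
#> 2 ring_2    O5    C1    C2    C3  54.26245     3      1
#> 3 ring_3    C1    C2    C3    C4 -54.26245     3      1
#> 4 ring_4    C2    C3    C4    C5  54.26245     3      1
#> 5 ring_5    C3    C4    C5    O5 -54.26245     3      1
#> 6 ring_6    C4    C5    O5    C1  54.26245     3      1
```

The targets are the torsions *measured* on this conformer (±54.26° for the
idealized ring; a real GlcNAc conformer measures 53.65° along O5–C1–C2–C3),
each unimodal with a tight 3.0° sigma. Validation of the same model:

```r
diagnose(fx$coords, fx$dictionary)
#> NAG: verdict 'yes' (4C1, Q = 0.550 A, theta = 0.0, phi = 0.0)
#>   [ok] anomeric     O1 substituent equatorial as expected for beta anomer
#>   [ok] chirality    all chiral centres match
#>   [ok] amplitude    Q = 0.550 A (window 0.35-0.90)
#>   [ok] conformation observed 4C1, expected 4C1

boat <- distort_ring(fx$coords, theta = 90, phi = 270, fraction = 1)
diagnose(boat, fx$dictionary)
#> NAG: verdict 'check' (1S5, Q = 0.550 A, theta = 90.0, phi = 270.0)
#>   ...
#>   [FAIL] conformation observed 1S5, expected 4C1
```

The distorted ring classifies as the ¹S₅ skew-boat and, because everything
else is intact, draws a `check` (high-energy pucker: verify against the
map). The toy regularizer shows what the unimodal restraints do in
refinement — the boat returns to the chair:

```r
res <- regularize(boat, restraints_from_dictionary(p))
res
#> ring_min: 65 iterations, final energy 2.465e-07, theta 0.0 deg
```

Without `ring_*` torsions (bonds/angles only) the boat survives, and a
strongly weighted, featureful density term generated from the boat holds
it in place — the data-versus-geometry trade-off in miniature.

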