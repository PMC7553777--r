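---
title: "Repeat-swap modeling and elevator-motion analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-swap modeling and elevator-motion analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repswap)
```

## The model

Elevator-type transporters with an internal two-fold inverted repeat have
a structural property that `repswap` exploits throughout: rotating the
protein 180° about *any* axis in the membrane plane produces, up to the
repeat labelling, an approximate model of the opposite-facing
conformation. The two repeats share a fold but opposite membrane
orientation, so the rotated copy superposes onto the original once the
repeats are exchanged in the atom correspondence. Three consequences
follow directly from the geometry and are implemented as exact contracts:

1. **Involution.** Applying the 180° rotation twice restores the original
   coordinates. `generate_swap_target()` builds the rotation matrix as
   `2ââᵀ − I`, which is an exact involution in floating point for an
   exactly unit axis.
2. **Magnitude preservation.** The transport domain's displacement along
   the membrane normal relative to the scaffold changes sign but not
   magnitude, so the planned displacement change is exactly −2× the
   initial displacement.
3. **Doubled spin.** If the state's transport domain is spun by θ about
   the membrane normal relative to the symmetric configuration, the
   repeat-swapped alignment of state onto target is a rotation by 2θ
   (with reversed handedness): conjugating a rotation about the membrane
   normal with a 180° in-plane rotation inverts its sense.

`plan_transition()` operationalises this: it generates the target,
re-poses it so the repeat-swapped *scaffold* matches the state's scaffold
(removing the arbitrary global frame introduced by the choice of in-plane
axis), then decomposes the repeat-swapped *transport-domain* fit into a
spin axis and angle, and takes the membrane-normal displacement delta
from the two posed structures. Because the in-plane rotation axis is
arbitrary, its choice is absorbed by the scaffold re-posing; the
displacement delta is invariant to it (a tested property), and only the
reported spin-axis direction retains the arbitrariness. The default axis
is the frame's x axis, recorded in the target's metadata for
reproducibility.

## Rigid-body core

Superposition uses the quaternion eigenvalue (Horn) formulation: the
optimal proper rotation is the dominant eigenvector of the 4×4 matrix
assembled from the weighted covariance of the centered coordinate sets.
This cannot produce a reflection, which is the behaviour wanted for
chiral molecules. An independent SVD (Kabsch) implementation with a
determinant correction lives in the test suite as the oracle; the two
agree to 10⁻⁹ Å RMSD over random noisy instances.

The spin angle of a group about a predefined axis â follows the
collective-variable convention: compute the *unconstrained* best-fit
quaternion `q = (w, v)` rotating the reference onto the group after
centroid removal, then report `2·atan2(v·â, w)` mapped to (−180°, 180°].
When the optimal rotation is exactly about â this equals the signed
rotation angle, and it is additive for successive rotations about the
same axis. Under coordinate noise it differs from the exact
axis-constrained optimum (which a brute-force grid scan in the tests
approximates at 0.01° resolution) by an amount that is typically a few
thousandths of a degree at σ = 0.05 Å for domain-sized groups, with a
tail reaching ~0.03° in about 1% of random configurations. This residual
is a property of the projection convention, not an implementation error,
and the convention is retained because it is the one used by biased-MD
engines.

Helix axes are the first principal component of the centered Cα
coordinates, signed N→C. A principal component of a helical coil is not
exactly the generating axis for short fragments: the covariance between
the axial coordinate and the Cα ring phase vanishes only asymptotically,
giving a bias of ≈2.3° at 12 residues that decays to ≈0.4° at 30 and
≈0.05° at 100 residues. Inter-helix *angle changes* between frames cancel
most of this bias because both endpoints carry it; the hinge-series tests
bound the end-to-end error at 1° for 10-residue helices. A cylinder fit
would remove the bias but is substantially less stable for the 8–12
residue hairpin segments this analysis needs, which is why the principal
component was chosen.

## Collective variables and restraints

Four variable kinds cover the transition: `spin_angle` (degrees),
`distance_z` (signed Å along the membrane normal between the transport
and scaffold group centroids), `orientation` (best-fit quaternion of the
scaffold against its reference, restrained to pin the global frame), and
`site_distance`. For the substrate variable the group definitions are
fixed (substrate non-hydrogen atoms; binding-site Cα atoms) but the
distance functional is a documented package choice: the distance between
the two group centroids. A minimum-pairwise-distance functional would
also be defensible; centroid–centroid was chosen because it is smooth,
cheap, and matches the "keep the substrate in the site" intent of a
half-harmonic wall at 2.0 Å.

`emit_colvars_config()` writes the restraint set with the staged
protocol's force constants — 8 kcal/mol/deg² (spin), 80 kcal/mol/Å²
(distance), 100,000 kcal/mol (orientation), wall at 2.0 Å with
1.0 kcal/mol/Å² (site) — and a four-phase schedule (transition to a
common reference state, hold, main transition, hold; defaults 10/10/100/50
ns) converted to step counts at a configurable timestep (default 2 fs).
Atom lists are emitted as 1-based serial numbers sorted ascending;
emission is byte-stable, and `parse_colvars_config()` round-trips every
constant, center and atom list exactly (a tested invariant). Phase
durations beyond the main transition are recorded as comments rather than
additional restraint blocks, since consecutive phases are separate runs
in practice and stacking multiple harmonics on one variable would change
the potential.

## Elevator-motion quantification

`quantify_elevator_motion()` follows a fixed decomposition order:
(1) superpose state B's scaffold onto state A's over backbone atoms
(N, CA, C, O); (2) carry all of B with that transform; (3) superpose the
transport domains (helix Cα) and report the rotation angle/axis;
(4) split the transport centroid displacement into its membrane-normal
component (`translation_z`, signed) and the in-plane residual. The
"repositioned by" headline number is the membrane-normal component, with
the in-plane residual reported separately rather than folded into a total.
Cross-homolog comparisons are supported by supplying two annotations whose
domain ranges are equal-length ordered residue-equivalence maps; the
package deliberately contains no sequence-alignment heuristics, so such
maps are curated externally. Domain fits here are unweighted (the groups
are already homogeneous Cα/backbone selections); trajectory alignment
(`align_trajectory()`), which mimics visualisation practice, uses
mass-weighted centers by default.

## The synthetic generator

`make_bundle()` constructs what the analysis assumes and nothing more:
per domain, `helices_per_domain` ideal α-helices (1.5 Å rise, 100°
twist, 2.3 Å radius — canonical values) placed on rings (scaffold 16 Å,
transport 7 Å radius); repeat 2 is repeat 1 rotated 180° about the
in-plane axis, making the core *exactly* repeat-swap symmetric; the
transport domain is then spun about the membrane normal through its own
centroid and lifted along the normal by the spec's ground-truth amounts.
Backbone N/C/O atoms are placed by a rigid per-residue rule along the
local Cα direction, so every Cα–C distance is exactly 1.52 Å and the
bond-length statistic is analytically checkable. Noise is isotropic
per-atom Gaussian with a recorded seed; the RNG state is restored after
generation. The default transform (37.4° spin, 13.0 Å lift) is the
elevator amplitude characteristic of a DASS outward→inward transition,
so the default bundle exercises the analysis at realistic magnitude.

What the generator does *not* emulate — side chains, sequence, loops
connecting helices, membrane environment, anharmonic thermal motion,
imperfect repeat symmetry — bounds what passing tests show: they validate
the geometry and the contracts, not robustness to the messiness of real
structures. In particular, real repeats are only approximately symmetric,
so on experimental structures the swapped-repeat fit has an intrinsic
RMSD floor (the target is approximate by design) and recovered spins
depend mildly on the curated domain boundaries. The four deposited-
structure checks in the acceptance suite exist for exactly that reason
and run whenever the experimental files are supplied locally.

`make_transition_trajectory()` interpolates the transport transform
either geodesically (`slerp_rigid`: per-frame spin exactly linear in
frame index, the ground truth for time-series tests) or by linear
Cartesian interpolation (`linear_cartesian`), whose midpoint spin
deviates measurably from half the angle — a feature used to pin the spin
evaluator against the grid oracle.

## Numerical choices and degenerate inputs

- Quaternions are stored `w ≥ 0`, normalised on construction to 10⁻⁹;
  rotations below 10⁻⁶ degrees report an undefined axis rather than a
  noise-directed one.
- Superposition requires ≥ 3 non-collinear atoms in each set (collinear
  sets leave a rotational degree of freedom); collinearity is detected by
  the second singular value at a 10⁻⁸ relative threshold. Helix-axis
  fitting accepts collinear traces (the axis is still defined) but
  requires ≥ 4 points and rejects coincident ones.
- Alternate locations resolve to the highest-occupancy conformer, ties
  broken by file order. Insertion-coded residues are distinct residues in
  file order. HETATM records are kept, flagged, and excluded from protein
  selections unless a selection names the residue explicitly.
- Residue ranges use author numbering, inclusive on both ends, matching
  how binding-site residues are quoted in structural papers.
- PDB coordinates are written to three decimals; one write/read round
  trip quantises coordinates (≤ 0.0005 Å), after which round trips are
  exact. Coordinates overflowing the fixed columns raise an error rather
  than corrupting the format.
- Angles are degrees everywhere (restraint constants are per degree²);
  distances are Å.

## Problem sizes

The test and acceptance computations run on bundles of 4 helices × 12
residues per domain (384–388 atoms), 100-instance superposition oracle
sweeps, 500-replicate Monte-Carlo envelopes for noisy recovery, and
1000-replicate noise-floor estimates for the swapped fit — sizes at which
every geometric property being asserted is already fully expressed, while
the whole suite completes in well under a minute.

## Limitations

The package quantifies and parameterises conformational transitions; it
does not run simulations, estimate free energies, build force-field
systems, or remodel side chains and loops on the swap target. Domain,
repeat and helix boundaries for experimental structures are user input by
design: deriving them automatically (by sequence or structure alignment)
would embed exactly the heuristics this geometric core is meant to stay
free of.
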