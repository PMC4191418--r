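---
title: "Rigid-body helical analysis and base-flipping free energies with stepflip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body helical analysis and base-flipping free energies with stepflip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepflip)
```

## What the package models

`stepflip` analyzes double- and triple-helical DNA at the base-pair step
level and computes base-pair opening free energies from umbrella-sampled
series of a periodic flipping coordinate.  Its two halves share one data
model (`dna_structure`: an atom table plus one or more coordinate frames):

1. **Rigid-body geometry.**  Each base is assigned an orthonormal frame by
   least-squares superposition of an idealized base geometry (ring atoms
   only) onto the observed coordinates.  Watson-Crick pair frames average
   the two base frames after flipping the complementary base (y and z
   negated), and consecutive pair frames yield the six step parameters
   (Shift, Slide, Rise, Tilt, Roll, Twist) in the symmetric mid-frame
   convention: the bending angle is split evenly about the hinge, twist is
   measured about the common z-axis, and translations are expressed in
   mid-frame axes.  The composition used by the synthetic builder is the
   exact algebraic inverse of this decomposition, which is what makes
   rebuild-then-analyze round trips exact to numerical precision rather
   than approximately.
2. **Opening thermodynamics.**  The flipping coordinate is the
   pseudo-dihedral over four centers of mass (flipping base, its sugar,
   the first neighboring sugar, the first neighboring base pair).
   Umbrella windows biased by `k/2 (x - x_i)^2` (minimum-image difference,
   radians) are unbiased by periodic WHAM; open/closed states are defined
   by the solvent accessibility of a reporter atom (H3 of pyrimidines, N1
   of purines), and the opening free energy integrates the Boltzmann
   density over the two states.

## Conventions and units

Distances are in Angstrom, angles in degrees, energies in kcal/mol, SASA
in nm^2 (matching the scale on which the accessibility threshold is
stated).  Frames are right-handed with det +1, asserted wherever a
rotation is produced.  Local helical parameters derive from the screw axis
of the step rotation: helical twist and rise are the rotation about and
translation along the axis; x/y-displacement locate the pair origin
relative to the axis; inclination and tip are the arcsines of the
projections of the pair's long and short axes onto the helical axis, so a
pure-twist step has zero displacement and zero inclination, positive roll
gives positive inclination, and negative slide gives negative
x-displacement.  Zp and Zp(h) project the step's inter-strand
phosphorus-phosphorus vector onto the mid-frame z-axis and the helical
axis respectively.  Steps with |Twist| within 5 degrees of 180 are flagged
`antiparallel` rather than silently unwrapped, and steps with numerically
zero net rotation return flagged `NA` helical parameters instead of an
arbitrary axis.

## The synthetic builder and what it emulates

The builder is the package's source of ground truth, not a test fixture:

* `rebuild_helix()` places idealized base geometries (the standard
  nucleic-acid reference frame fixture) by composing step transforms.
  Canonical fiber parameters are `canonical_step_parameters()`: B-form
  Twist 36.0 deg, Roll 0.6 deg, Rise 3.32 A; A-form 31.1 deg, 8.0 deg,
  3.31 A.  Slide defaults (0 for B, -1.5 A for A) are the field-standard
  fiber values.  Two deliberate additions to the published heavy-atom
  fixture are labelled synthetic in the geometry table: thymine's H3
  (placed 1.03 A from N3 along the idealized hydrogen-bond direction,
  needed as the SASA reporter) and a single pseudo-phosphate per
  nucleotide at an idealized B-like radius (~9 A), which supports groove
  and Zp analyses.  Because the backbone is reduced to that one
  pseudo-atom, *absolute* groove widths are approximate; *comparisons*
  between structures built with the same convention are meaningful.
* `build_triplex()` adds an antiparallel purine-motif third strand.  Each
  TFO base is placed by a fixed planar transform relative to its target
  purine's frame: the base plane is flipped (trans pairing) and the
  in-plane rotation/translation is derived once per triplet type by
  matching the idealized donor-acceptor distances (2.9 A) of the
  reverse-Hoogsteen bonds (G: N1 to N7 and N2 to O6; A: N6 to N7 and N1
  to N6) with a soft steric penalty.  There is no closed-form target for
  a relaxed triplex geometry, so the construction is validated by what
  can be checked: H-bond distances within 2.7-3.1 A and no non-bonded
  heavy-atom contact below 2.0 A.
* `sample_step_ensemble()` draws per-step parameters from Gaussians with
  configurable mean and 6x6 covariance.  `deformability_covariances()`
  encodes the known deformability ordering (pyrimidine-purine steps most
  flexible, purine-purine intermediate, purine-pyrimidine most rigid) as
  class-scaled diagonal covariances (baseline SDs 0.4/0.35/0.25 A and
  3/4/4 deg; scales YR 1.5, RR/YY 1.0, RY 0.6).  These values are chosen
  as realistic room-temperature fluctuation scales for B-DNA steps; they
  are generator settings, not fitted quantities.
* `sample_biased_windows()` is a seeded Metropolis walk on the periodic
  coordinate, one lockstep chain per window, with the proposal width
  adapted during burn-in toward 30-60% acceptance.  Fidelity of dynamics
  is irrelevant here; only the stationary distribution matters for WHAM.
  Records can be thinned to reduce autocorrelation.

What the generator does *not* emulate: solvent and ions, backbone
torsional realism, sequence-dependent coupling between parameters
(covariances are diagonal by default), and the slow collective modes of a
real trajectory.  Passing tests therefore demonstrate correctness of the
analysis machinery on data with known truth, not agreement with any
particular simulated or experimental ensemble.

## Ensemble statistics

Region statistics follow two-stage averaging (per-step time averages,
then the region mean over steps).  The SEM comes from blocked averaging
of the per-frame region series with doubling block sizes; the reported
value is the first plateau (relative SEM change below 5%), falling back
to the largest block when no plateau appears.  Fewer than eight frames is
an error rather than a silent unblocked estimate.

Groove widths are raw inter-strand phosphorus-phosphorus distances (no
van-der-Waals correction) with configurable cross-strand offsets
(defaults -2 for the minor and +2 for the major groove); base pairs whose
partner falls off the helix are reported `NA` rather than extrapolated.
Stacking overlaps project each base pair's polygon (convex hull of ring
atoms, optionally extended by the exocyclic substituents) onto the step
mid-frame xy-plane and intersect the two convex polygons exactly
(Sutherland-Hodgman).  Bend angles use the centers of mass of the two
Watson-Crick bases only (no sugars or phosphates).  PCA superposes every
frame onto the first frame by the fit region's atoms (unweighted
coordinates), then spectrally decomposes the coordinate covariance;
eigenvalues are reported for all 3N degrees of freedom with zeros beyond
the ensemble rank.  The superposition removes rigid-body motion, so a
planted displacement vector is recovered up to its rigid-body component.

## WHAM and the opening free energy

The WHAM implementation iterates the window constants as a damped fixed
point until the largest change is below the tolerance (default 1e-6
kcal/mol; iteration cap 1e6 with a hard error on non-convergence), on a
periodic grid of 720 bins by default with 72 windows spaced 5 degrees
apart and `k = 2000` kcal/(mol rad^2).  Bias energies are evaluated at
bin centers; with these settings the remaining discretization bias is
small against the statistical noise at desk-scale sample counts.  Bins
never visited are masked with a warning and excluded from derived
quantities.  Per-bin errors split each window's series into four
contiguous parts, re-run WHAM per part warm-started from the full-data
constants, anchor all four profiles at the full profile's minimum bin,
and take the per-bin standard deviation.

The open/closed partition is derived from geometry: window-representative
conformations are generated by rotating the flipping base rigidly about
the sugar-sugar axis (which advances the pseudo-dihedral by exactly the
applied angle), each conformation is classified by reporter SASA, and the
window labels are transferred to the profile grid by nearest window
center with ties resolved toward closed (conservative for the opening
cost).  A fixed angular cut is available as an alternative partition.
`delta_g_open()` is invariant under adding a constant to the profile;
`barrier()` reports max minus min, plus the per-direction barriers toward
positive (major-groove) and negative (minor-groove) angles.

SASA uses Shrake-Rupley with a deterministic golden-spiral point set (960
points per atom) and per-element radii of 0.14 nm (C), 0.13 nm (O, P),
0.10 nm (H), interpreted as atomic radii rolled with a zero additional
probe; nitrogen, not quoted alongside the others, defaults to 0.13 nm.
The closed threshold is 0.001 nm^2.  For structures built by this
package's reduced atomic model, burial of the reporter requires the
alternative configuration (uniform 0.14 nm water probe on top of the
radii, `open_close_definition(probe = 0.14)`): with only base atoms, one
C1' and one pseudo-phosphate per nucleotide, zero-probe spheres slip
through gaps a water molecule cannot enter.  Both configurations are one
argument apart; full-resolution structures can use the zero-probe
default.

## The example system and demo surface

The bundled system is a 30-mer duplex
(5'-AACTGCTAAAGAGGGAGGGACTTGATGTAT-3') whose homo-purine stretch (base
pairs 11-20) binds the antiparallel 10-mer TFO 5'-AGGGAGGGAG-3'; leading
strand residues are 1-30, complementary 31-60 (partner of i is 61 - i),
TFO 61-70.  The reference mid-helix region defaults to base pairs 11-20.
The TFO-bound homo-purine step parameters (Twist 33.1 deg, Roll 5.6 deg,
Rise 3.30 A, Slide -1.5 A) reflect the B-to-A-ward shift that
accompanies third-strand binding; with them, the rebuilt triplex's
homo-purine major groove comes out about 2 A wider than the plain
duplex's while the flanking regions are untouched — the direction and
rough size of the effect follow from lower twist plus negative slide, not
from any fit.

The demo flipping surface is `double_well_pmf(dg = 3, b = 4)`:
`W(x) = b/2 (1 - cos 2x) + dg/2 (1 - cos x)`, a closed well at 0 degrees,
an open well at 180 degrees, and a barrier near 5.5 kcal/mol.  The
moderate amplitudes keep every umbrella window populated at desk-scale
sample counts (5e4 samples per window in the acceptance runs, thinned by
3), so recovery errors are dominated by counting noise rather than
unsampled regions.  Real flipping barriers are two to three times larger;
recovering them would need proportionally longer sampling, not different
machinery.

## Numerical choices and edge cases

* Rotations are validated (orthonormality to 1e-8, det +1) at
  construction; the near-180-degree axis extraction uses the symmetric
  part of the rotation matrix to stay stable.
* The screw-axis point is the minimum-norm solution of the singular
  linear system via SVD pseudo-inverse, which fixes the component along
  the axis without affecting displacement values.
* Frame fitting requires at least three matched, non-collinear ring atoms
  and reports missing atom names; collinearity is detected by the second
  singular value of the centered coordinates.
* Ensembles are drawn with per-step eigendecomposition roots; a negative
  eigenvalue beyond round-off rejects the covariance.  Rise values are
  floored at 0.1 A to keep degenerate draws physical.
* PDB I/O is delegated to bio3d; a validation pass rejects malformed
  ATOM/HETATM records (naming the line) and MODEL blocks whose atom
  records differ, and writing refuses coordinates that overflow the
  fixed-width field.
* Problem sizes in the test suite (ensembles of 60-600 frames, windows
  of a few thousand samples, 5e4 per window in the acceptance run) were
  chosen so each check resolves its stated tolerance with margin.

## Known limitations

* The reduced backbone (one pseudo-phosphate, no sugars beyond C1')
  makes absolute groove widths and absolute SASA values approximate;
  both are intended for within-convention comparisons.
* The reverse-Hoogsteen placement is an idealized rigid construction,
  validated only by H-bond distance ranges and clash limits.
* Hoogsteen "steps" are analyzed over TFO-only base frames by default
  (the TFO-purine pair-frame variant is available through the same
  machinery).
* WHAM assumes uncorrelated samples within windows; the Metropolis
  sampler's residual autocorrelation inflates the blocked errors, which
  is the honest place for it to appear.
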