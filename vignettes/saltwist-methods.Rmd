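---
title: "Measuring DNA twist at high salt: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DNA twist at high salt: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltwist)
```

## The scientific problem

DNA is a polyanion, and its helical twist — the rotation between successive
base pairs, in degrees per base pair — depends on the ionic environment.
Single-molecule magnetic tweezers measure twist changes by winding a
torsionally constrained DNA tether: plotting extension against applied turns
gives a "hat curve" whose center marks the torsionally relaxed state. When
the salt concentration changes, the whole curve shifts along the turns axis,
and the shift converts directly into a twist change per base pair. A
long-standing question is whether very high alkali-chloride concentrations
(several molar, especially LiCl) drive the canonical B-form helix into the
over-twisted C-form seen in dehydrated fibers — a change of 2–3 degrees per
base pair — or whether the twist response saturates far below that.

`saltwist` implements the complete analysis chain used to answer this kind
of question: hat-curve twist quantification, base-pair-step helical geometry
and backbone-substate analysis of atomic structures, inner-sphere cation
counting, Kirkwood–Buff solution thermodynamics, and singular value
decomposition of circular dichroism (CD) spectra series. Because neither a
tweezers instrument nor molecular-dynamics trajectories are available to a
test suite, every input class has a seeded synthetic generator that records
its planted ground truth; the package is validated by round-tripping those
plants through the analyzers.

## Hat-curve twist quantification

The synthetic rotation–extension curve is piecewise: a quadratic cap of
half-width `buckling_offset` turns around the center at the plateau
extension, and linear plectonemic arms with the planted slopes beyond, value-
and slope-continuous at the buckling points. Only the linear arms carry
information used by the estimator; the cap shape is a smoothness convenience,
not a mechanical model of the pre-buckling regime (no worm-like-chain
fitting is attempted).

Defaults describe a 20.6 kbp tether (`n_bp = 20600`; the construct length is
only known to 0.1 kbp, so the round number is used) sampled in 5-turn steps
at 0.25 pN, plateau 5.5 µm, slopes 45 nm/turn, buckling offset 25 turns,
extension noise 20 nm per point, and a turn window of ±120 turns — wide
enough for well-populated arms while keeping the model extension positive
everywhere.

`segment_plectonemic()` estimates the plateau as the mean of the three
largest extensions and takes points below 0.85 of it on each side of the
maximum (the threshold is a package choice; curves with fewer than three
points on either side are rejected, as an unsuitable tether would be).
`fit_hat()` fits one ordinary least-squares line per side, in nm versus
turns, and defines the curve center as the abscissa of the two lines'
intersection, with a standard error propagated from both fit covariances.
This intersection definition is parameter-free; a `method = "midpoint"`
variant (midpoint of the lines' crossings with the plateau) is provided and
coincides with it for symmetric slopes. With asymmetric slopes the
intersection of the generator's arm lines sits at
`b (s_pos − s_neg) / (2 (s_pos + s_neg))` from the cap center, which the
tests assert in closed form.

The twist change between a condition and the 100 mM KCl reference is

\[ \Delta Tw = (c - c_{\mathrm{ref}}) \cdot 360 / N_{\mathrm{bp}} \quad
   [^\circ\,\mathrm{bp}^{-1}], \]

positive when the curve shifts to larger turns. `recover_table()` simulates
a full measurement campaign — per molecule one test and one reference curve,
both fit independently — and aggregates an unweighted mean ± SD over
molecules (matching how multi-molecule tweezers tables are reported, rather
than inverse-variance weighting). Force calibration follows the
equipartition theorem, \(F = k_B T\, L / \mathrm{var}(x)\), with \(k_B T\)
evaluated at 295.15 K (~22 °C room temperature).

The concentration dependence of \(\Delta Tw\) is fit as
\(a + b\,c^{\alpha}\) by weighted least squares over `c <= 2` M, either with
\(\alpha\) fixed at 0.5 (the square-root law that describes the low-to-
intermediate regime) or with \(\alpha\) profiled by one-dimensional
optimization.

## The duplex builder as ground truth

Structures are generated directly from helical parameters rather than from
fiber-diffraction atom lists: a per-nucleotide template is placed by a rigid
screw — base pair *i* rotated by the cumulative planted twist about the
global z axis and translated by the cumulative rise. The default sequence is
the 33-mer duplex used throughout the analyses (stored reference-strand
5'→3'). B- and C-like geometries are planted as 9.97 and 9.30 base pairs
per turn (36.1 and 38.7 degrees per base pair); atom-exact reproduction of
published fiber models is out of scope, since only the planted twist matters
downstream.

Each nucleotide carries a minimal atom set: the phosphate group (P exactly
at the planted backbone radius, default 9.4 Å, with OP1/OP2 pointing
outward), a five-membered sugar ring, O5'/C5'/O3' linkage atoms, and a
planar base anchor — the glycosidic nitrogen, two base-plane atoms
(N9/C8/C4 for purines, N1/C6/C2 for pyrimidines) and C1'. The complementary
strand is the template mapped through the base-pair dyad, so chain B residue
*i* pairs with chain A residue *i* (chain B runs antiparallel; its 5'→3'
successor is residue *i − 1*).

Sugar pucker is planted with two rigid ring templates: a regular pentagon
with Cremer–Pople-style out-of-plane displacements whose phase offset is
solved (deterministically, by grid search plus refinement) so the
Altona–Sundaralingam pseudorotation phase of the resulting torsions is
exactly 162° (C2'-endo) or 18° (C3'-endo). Exact ring closure from target
torsions is deliberately not solved; the rigid template suffices for a
round-trip test. Backbone substates are finalized in canonical BI: every
linkage's ζ is set by rotating the successor's O5' about the O3'–P bond so
that the wrapped ε − ζ equals −90°. Because only O5' moves, phosphates stay
at the planted radius; the price is that the C5'–O5' distance is not
maintained, which nothing downstream consumes. The 5'-terminal O5' of each
strand has no preceding linkage and keeps its raw template position.

`perturb_ensemble()` turns the duplex into a synthetic "trajectory": per
frame the duplex is regenerated with per-step twist jitter (N(0, σ²) per
step), each scored nucleotide (terminal three base pairs excluded, matching
the analyzer) is drawn into BII with probability `bii_fraction` and planted
by the same ζ rotation at +90°, and isotropic Gaussian coordinate noise is
added last. A noiseless all-BI ensemble is bit-identical to the builder.

## Frame-based helical descriptors

`base_pair_frames()` fits the fixed four-atom anchor template to each base
by rigid superposition (Horn's quaternion method; C1' is lifted off the base
plane so the fit is unique), flips the complementary frame's y/z axes, and
averages the two rotations with a projection back onto SO(3). Twist and
rise follow the standard mid-frame construction: for consecutive frames with
relative rotation `R = t(F_i) F_{i+1}`, the mid-frame is `F_i` composed with
half of `R`; twist is the signed angle between the x axes projected onto the
plane normal to the mid-frame z, rise the origin displacement along it. On
builder output this round-trips the plants to numerical precision; averages
exclude three terminal base pairs at each end (excluding four changes the
mean of a uniform duplex by less than 1e−9).

Two propagation facts are worth knowing. First, the four-atom anchor fit
has a short lever arm, so coordinate noise amplifies: 0.1 Å of isotropic
jitter moves frame origins by ~0.25 Å RMS and perturbs single-step twists
by a degree or more at 0.05 Å noise — per-step twist comparisons in the
tests therefore use noiseless ensembles, while mean twists average the noise
away. Second, BI/BII classification from ε − ζ (BII iff the wrapped
difference is ≥ 0°, a closed boundary) is robust up to ~0.1–0.2 Å of
coordinate noise; beyond that, torsion noise tails start flipping states,
which is why the ensemble default is `coord_noise_sd = 0.05` Å.

The "DNA radius" is defined here as the RMS distance of phosphorus atoms to
the helix axis (the total-least-squares line through the pair-frame
origins), terminal base pairs excluded; other tools define radius
differently, and no cross-tool numerical identity is claimed. Inner-sphere
cation counting follows the trajectory convention: per frame, every cation
within 0.3 nm of at least one non-bridging phosphate oxygen counts once (an
ion close to both OP1 and OP2 is a single ion), normalized per phosphate
(every residue carries a 5'-phosphate, so a 33-mer has 66) and averaged
over frames.

Conformational clustering is the classic neighbor-count scheme: all pairwise
minimal RMSDs (Kabsch superposition with a reflection guard, backbone heavy
atoms by default), iteratively removing the structure with the most
neighbors within 0.5 nm together with its neighbors; ties break to the
lowest frame index, and the center of the largest cluster is the
representative conformation.

## Ion placement

`place_ions()` plants exactly `round(ions_per_phosphate × n_phosphates)`
shell cations at uniform distances within `shell_range` (default
0.19–0.25 nm) of non-bridging oxygens, visiting phosphates cyclically and
alternating OP1/OP2, with isotropic directions, plus bulk ions uniform in a
box and excluded from within 0.5 nm of the DNA. No two ions come closer
than 0.15 nm (rejection sampling). These placement details are
deliberately simple — they do not affect counting, which only depends on
shell distances — and a `shell_range` reaching the 0.3 nm counting cutoff
triggers a warning, since planted ions would silently stop being counted.

## Kirkwood–Buff thermodynamics

Kirkwood–Buff integrals are computed from tabulated radial distribution
functions by the composite trapezoid rule,
\(G = 4\pi \int_0^{R_c} (g(r) - 1)\, r^2\, dr\), with a tail-window average
of the running integral (default window 0.3 nm) as a guard against
truncation ripple; no finite-size extrapolation is attempted. The synthetic
RDF generator offers an ideal model, a square well (whose analytic integral
\(4\pi\Delta (r_{hi}^3 - r_{lo}^3)/3\) is the planted truth; grid points on
the discontinuity carry the mean of the two sides so the trapezoid rule is
exact to O(dr²)), and Gaussian peaks with a closed-form integral.

The activity derivative of the binary 1:1 electrolyte uses the convention

\[ a_{cc} = \frac{1}{1 + \rho_c (G_{cc} - G_{ca})}, \]

which is 1 in the ideal limit. Conventions differ between authors in how
like-ion integrals are symmetrized and indistinguishability is treated, so
`activity_derivative()` takes a pluggable `formula` hook; under the adopted
form, increasing the cation–anion integral at fixed \(G_{cc}\) increases
\(a_{cc}\), and the property tests assert exactly that sign. Molality is
converted to molarity from the averaged box volume via
\(n_{\mathrm{salt}} = m\, n_{\mathrm{water}} M_w\) (with
\(M_w = 0.0180153\) kg/mol) and \(c = n_{\mathrm{salt}} / (N_A V)\).
`twist_vs_activity()` re-maps twist-change records from the concentration
axis to the activity-derivative axis by linear interpolation (never silent
extrapolation — out-of-range records are flagged) and reports a plateau
estimate: the smallest \(a_{cc}\) beyond which the local slope stays below
a tenth of the initial slope.

## CD spectra series

The generator composes a B-form-like basis spectrum (positive bands near
225 and 280 nm, negative near 250 nm) with a salt-response basis whose
weight grows as \(\sqrt{c}\), normalized to zero at the 0.1 M reference and
scaled so the 280 nm band changes sign near 4.5 M; Gaussian noise is added
per matrix element. `svd_decompose()` performs a full SVD of the uncentered
matrix (no preprocessing is assumed; column centering is available by flag)
and estimates the signal rank as the number of singular values above a
noise floor computed from the trailing half of the spectrum as median +
5·MAD — a package choice, where a visual judgement would otherwise be made.
`band_trend()` extracts the band at the grid wavelength nearest 280 nm,
references it to 0.1 M, fits the square-root law and a free-exponent
variant, and locates sign changes by linear interpolation in concentration.

## What the synthetic data do and do not emulate

The generators reproduce the *estimands* of real experiments — planted curve
centers and slopes, planted helical parameters, substate fractions, shell
occupancies, analytic Kirkwood–Buff integrals, planted spectral weights —
under Gaussian noise. They do not emulate: sequence-dependent twist
heterogeneity (jitter is i.i.d. per step), the worm-like-chain shape of the
pre-buckling cap, instrument drift or tracking artifacts, torque-induced
melting, chemically exact sugar/backbone covalent geometry, real ion
correlations (shell placement is geometric, not energetic), or solvent
degrees of freedom. Passing tests therefore demonstrate that the estimators
recover what they are designed to estimate at realistic noise levels — not
that any force field or instrument is accurate.

## Numerical choices and degenerate inputs

- Angles wrap to (−180°, 180°]; torsions follow the IUPAC sign convention.
- Parallel plectonemic lines (slope difference below 1e−9 nm/turn) have no
  intersection and error out; single-sided curves are rejected.
- A planar sugar ring (ν₂ = 0 with zero numerator) has an undefined
  pseudorotation phase and is reported per nucleotide.
- Superposition needs at least two atoms; reflections are excluded by the
  determinant guard.
- The activity-derivative denominator must be positive; a non-positive value
  is reported as thermodynamically unstable input.
- Kabsch/cluster tie-breaks: the lowest frame index wins; clustering is
  deterministic given input order.
- Seeds: every generator is bit-reproducible given its seed;
  `recover_table()` derives per-molecule seeds from the master seed in
  double precision to avoid 32-bit overflow.

## Problem sizes used in the checks

The test suite and the acceptance script run, per condition, 11 molecules ×
(test + reference) hat curves of 49 points each; a full-table reconstruction
covers all 32 tabulated salt/concentration conditions. Structure checks use
the 33-bp duplex (924 atoms); the clustering check uses 100 frames (4950
pairwise superpositions on 726 backbone atoms); fit-coverage checks use 100
seeded repeats; force-calibration recovery uses 3480 fluctuation samples
(58 Hz × 60 s). These sizes were chosen as the smallest that exercise every
estimator at realistic statistics.

## Known limitations

- The builder's bases are idealized anchors, not full heterocycles; analyses
  requiring real base geometry (stacking energetics, groove widths, roll or
  slide) are out of scope, as is the full six-parameter step decomposition.
- Frame fitting uses a common anchor template for all bases; numerical
  identity with other helical-analysis software on arbitrary PDB files is
  not claimed (round trips on builder output are the contract).
- The Kirkwood–Buff activity convention is exactly that — a convention;
  users comparing against a source using a different symmetrization should
  supply it through the `formula` hook.
- The hat-curve cap is phenomenological; slopes and centers are the only
  quantities read off the curve.
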