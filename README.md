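# saltwist

DNA twist and helical structure at high alkali salt concentrations: an R
analysis pipeline for magnetic-tweezers rotation curves, base-pair-step
helical geometry, ion adsorption, Kirkwood–Buff solution thermodynamics, and
circular-dichroism spectra series — with seeded synthetic-data generators
that make the whole chain testable without instrument or simulation data.

## The problem

DNA twist (Tw, degrees per base pair) depends on the ionic environment. In
magnetic tweezers, a torsionally constrained tether traces a "hat curve" of
extension versus applied turns; past the buckling transition the extension
falls linearly as plectonemes grow. When the salt changes, the curve shifts
along the turns axis, and the shift between curve centers converts into a
twist change relative to a reference condition (100 mM KCl):

    ΔTw = (center − center_ref) · 360 / N_bp        [° bp⁻¹]

Whether multi-molar LiCl drives solution DNA toward the over-twisted C-form
(~2–3° bp⁻¹ above B-form) is tested by comparing the measured ΔTw — which
saturates below ~0.9° bp⁻¹ — against C-form expectations, and by structural
descriptors that distinguish B from C: mean step twist (36.1 vs 38.7° bp⁻¹
for ideal fiber geometries at 9.97 vs 9.30 bp/turn), BI/BII backbone
substates (BII iff wrapped ε − ζ ≥ 0°), sugar pucker phase, helix radius,
inner-sphere Li⁺ per phosphate (0.3 nm cutoff to non-bridging oxygens), and
neighbor-count conformational clustering at a 0.5 nm RMSD cutoff. Solution
thermodynamics enters through Kirkwood–Buff integrals of ion–ion radial
distribution functions and the activity derivative
a_cc = 1 / (1 + ρ_c (G_cc − G_ca)), used to place twist changes on the
activity scale instead of the concentration scale.

For whom: single-molecule biophysicists analyzing rotation–extension data,
and simulators validating helical/backbone analyses and electrolyte
thermodynamics against planted ground truth.

## Worked example

```r
library(saltwist)

# Recover a planted twist change from 11 synthetic molecules (20 nm noise)
recover_table(data.frame(salt = "LiCl", concentration = 4, delta_tw = 0.74),
              n_molecules = 11, noise_sd = 20, n_bp = 20600, seed = 1)
#>   salt conc_M delta_tw_deg_per_bp      sd  n planted n_failed
#> 1 LiCl      4               0.739 0.00506 11    0.74        0

# Helical analysis of an ideal C-form-like 33-mer duplex
d <- build_duplex(helix_spec(bp_per_turn = 9.30, rise = 3.38))
mean_step_params(d, exclude_terminal = 3)$twist   # 38.71 deg/bp
helix_axis_and_radius(d)$radius                   # 9.40 A

# Two inner-sphere cations per phosphate, counted at the 0.3 nm cutoff
ions <- place_ions(d, ion_spec(ions_per_phosphate = 2, n_bulk = 100, seed = 1))
count_adsorbed(d, ions, cutoff = 0.3)             # 2

# Activity derivative from synthetic RDFs (square wells, analytic truth)
rdf <- gen_rdf(rdf_spec("square_well",
  params = list(cc = list(r_lo = 0.2, r_hi = 0.4, delta = -0.4),
                ca = list(r_lo = 0.2, r_hi = 0.4, delta = 0.6))))
activity_derivative(kb_integral(rdf, "cc")$G, kb_integral(rdf, "ca")$G,
                    rho_c = 2.65)                 # 2.643

# CD series: SVD rank and the 280 nm band trend
set <- gen_cd_set(cd_spec(noise_sd = 0.02, seed = 1))
svd_decompose(set)
#> cd_svd: estimated signal rank 2; singular values 39.81, 17.05, 0.2588, ...
band_trend(set)
#> band_trend @ 280 nm: b = -1.2907 (sqrt law), free exponent 0.496;
#> sign changes at 4.51 M
```

Reading the numbers: the planted 0.74° bp⁻¹ twist change is recovered as
0.739 ± 0.005 over 11 molecules; the 9.30 bp/turn duplex analyzes to
38.71° bp⁻¹ mean step twist at the planted 9.4 Å phosphate radius; the
planted two-ion shell counts exactly 2 per phosphate; the synthetic spectra
are rank-2 with the second component's weight growing as √c (free exponent
0.496) and the 280 nm band changing sign near 4.5 M.

The published multi-salt twist-change table bundled for planting and
power-law fits is available as `alkali_twist_reference()`; a command-line
front end for all stages lives at `inst/scripts/twistbench` (see
`run_pipeline()`).

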