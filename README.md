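# poremech

Quantitative analysis of membrane stability against transmembrane pore
formation, for membrane biophysicists and simulators who want to go from
free-energy profiles, particle configurations and elastic-parameter tables
to the two numbers that characterize a membrane's resistance to poration:
the **pore nucleation free energy** ΔG<sub>nuc</sub> and the **line
tension** γ along the rim of an open pore.

## What it computes

Pore formation in a lipid bilayer proceeds from local thinning, through a
thin transmembrane water wire, to a toroidal open pore.  `poremech`
implements the analysis layer of that picture:

* **Pore reaction coordinate ξ<sub>p</sub>** on annotated particle
  configurations: for ξ<sub>p</sub> ≲ 1 the fractional connectivity of a
  polar transmembrane defect (per-slice occupancy of an analysis cylinder
  across the hydrophobic core); for ξ<sub>p</sub> ≳ 1 the pore radius in
  units of the nucleated-pore radius R₀ ≈ 0.4 nm, so ξ<sub>p</sub> = R/R₀.
* **PMF analysis**: ΔG<sub>nuc</sub> as the free-energy profile G(ξ<sub>p</sub>)
  interpolated at ξ<sub>p</sub> = 0.92 (the water-wire state); γ from an
  ordinary-least-squares fit of G against R = ξ<sub>p</sub>R₀ over the
  linear large-pore regime 4 ≤ ξ<sub>p</sub> ≤ 6.5, using
  dG/dR = 2πγ (classical nucleation theory,
  ΔG<sub>CNT</sub> = 2πRγ − πR²σ); metastable-pore detection (local minima
  at ξ<sub>p</sub> > 1); bootstrap standard errors; hysteresis between
  opening and closing profiles.
* **Continuum (Helfrich–Kozlov–Hamm) elasticity**: the monolayer energy
  density ½κ(H̃ − J<sub>s</sub>)² + ½κ<sub>θ</sub>t² + κ̄K̃<sub>G</sub>,
  the closed-form rim line tension
  γ<sup>bend</sup> = κd<sub>hc</sub>(π/4)(2/d<sub>hc</sub> − J<sub>s</sub>)²,
  its numerical quadrature over a torus rim, area rescaling
  ΔG<sup>exp</sup> = ΔG − k<sub>B</sub>T ln(A<sub>exp</sub>/A<sub>sim</sub>),
  pore probabilities exp(−ΔG/k<sub>B</sub>T), and labelled correlation
  analysis across membranes.
* **Elastic moduli from fluctuations**: tilt modulus κ<sub>θ</sub> and
  bending modulus κ from the Gaussian statistics of lipid tilt vectors
  t = d/(n·d) − n and pair splay; spontaneous curvature J<sub>s</sub> from
  the first moment of a lateral stress profile; hydrophobic thickness from
  tail/water density crossings.
* **Lateral sorting**: cylindrical per-species density maps ρ(r, z) around
  the pore axis, bulk-normalized maps, radial profiles and rim
  enrichment/depletion factors.
* **Synthetic data with known ground truth** for all of the above: toy
  flat/water-wire/open-pore membranes, Boltzmann-sampled tilt and splay,
  analytic stress profiles, and PMFs with prescribed ΔG<sub>nuc</sub>, γ,
  and metastable wells — the whole pipeline is testable without running
  molecular dynamics.

All user-facing functions take and return tibbles (or tibble-backed
classes) and compose with the pipe; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(poremech)

# A synthetic umbrella-style PMF with known ground truth: line tension
# 40 pN, nucleation barrier 90 kJ/mol, 2 kJ/mol point noise.
pmf <- make_synthetic_pmf(gamma_true = 40, dG_nuc_true = 90,
                          noise_sd = 2, seed = 1)
fit <- fit_pore_energetics(pmf, n_boot = 200, seed = 2)
fit
#> Pore energetics
#>   dG_nuc  = 91.22 kJ/mol +/- 2.47  (PMF at xi = 0.92)
#>   gamma   = 40.01 pN +/- 0.21  (fit 4 <= xi <= 6.5, r^2 = 0.9988)
#>   no metastable open pore
```

The fit recovers both ground-truth values within their bootstrap errors:
the barrier against forming a water wire (91 ± 2.5 kJ/mol) and the
free-energy cost per unit rim length of widening the pore (40.0 ± 0.2 pN).

A 90 kJ/mol barrier measured in a small simulation-sized membrane patch
(~83 nm²) translates to an organelle-scale membrane of 1000 µm²:

```r
rescale_nucleation_energy(90, area_exp = 1e9, area_sim = 83)
#> [1] 47.97563
pore_probability(48)
#> # A tibble: 1 x 3
#>      dG   probability order
#>   <dbl>         <dbl> <dbl>
#> 1    48 0.00000000817    -9
```

i.e. even a comparatively soft organelle membrane keeps the spontaneous
pore probability at the 10⁻⁹ level.  On the continuum side, the bending
moduli of a POPC monolayer predict the rim penalty directly:

```r
helfrich_line_tension(kappa = 33.7, d_hc = 2.85, J_s = -0.001)
#> [1] 61.86159   # pN
```

The reaction coordinate classifies generated membrane states; a thin
spanning water wire sits exactly at the nucleated state ξ<sub>p</sub> = 1:

```r
wire <- make_water_wire(100, c(POPC = 1), box_xy = 8, d_hc = 2.8, seed = 5)
xi_report(wire)
#> # A tibble: 1 x 6
#>   xi_chain R_hat  xi_p n_polar center_x center_y
#>      <dbl> <dbl> <dbl>   <int>    <dbl>    <dbl>
#> 1        1 0.309     1      28      3.5      3.1
```

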