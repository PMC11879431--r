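---
title: "Membrane pore energetics: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane pore energetics: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremech)
```

# The physical picture

A lipid bilayer resists transmembrane pore formation in two distinct ways.
First, nucleating a pore requires pushing polar material through the
hydrophobic core: thinning, then a single-file water wire.  The cost of
reaching the wire state is the nucleation free energy
$\Delta G_\mathrm{nuc}$.  Second, once a toroidal pore is open, widening it
costs free energy in proportion to the rim length: the line tension
$\gamma$.  For a wide pore classical nucleation theory gives

$$\Delta G_\mathrm{CNT}(R) = 2\pi R \gamma - \pi R^2 \sigma ,$$

so in the absence of lateral tension ($\sigma = 0$, appropriate for
constant-pressure, fixed-lipid-number conditions) the free-energy profile
grows linearly in the pore radius $R$ with slope $2\pi\gamma$.

Both quantities are read off a potential of mean force (PMF) $G(\xi_p)$
along a joint nucleation/expansion coordinate $\xi_p$: below 1 the
fractional connectivity of the polar defect, above 1 the pore radius in
units of the nucleated-pore radius $R_0 \approx 0.4\,$nm, i.e.
$\xi_p = R/R_0$.

On the continuum side, the Helfrich–Kozlov–Hamm (HKH) monolayer energy

$$F = \int \mathrm{d}A \left[ \tfrac{\kappa}{2}\big(\tilde H - J_s\big)^2
      + \tfrac{\kappa_\theta}{2} t^2 + \bar\kappa \tilde K_G \right]$$

links the PMF-derived quantities to measurable lipid properties: the
bending modulus $\kappa$, spontaneous curvature $J_s$, tilt modulus
$\kappa_\theta$ and (optionally) Gaussian modulus $\bar\kappa$.
Integrating the bending term over a rim whose tube curvature is
$2/d_{hc}$ (with $d_{hc}$ the hydrophobic thickness) and whose in-plane
curvature is negligible for a wide pore yields the closed form

$$\gamma^\mathrm{bend}_\mathrm{Helf} = \kappa\, d_{hc}\, \frac{\pi}{4}
  \left(\frac{2}{d_{hc}} - J_s\right)^2 ,$$

implemented in `helfrich_line_tension()` and checked numerically by
`rim_quadrature_line_tension()`.

# The coordinate $\xi_p$ on particle configurations

`slice_occupancy()` counts polar particles per $z$-slice of an analysis
cylinder across the hydrophobic core; the slice indicator is a linear ramp
$\delta_s = \min(1, n_s/n_\mathrm{sat})$ and
$\xi_\mathrm{chain} = N_s^{-1}\sum_s \delta_s$.  Defaults: cylinder radius
1.2 nm, slice thickness 0.1 nm, $n_\mathrm{sat} = 1$, core bounds from the
tail-density region (bins above half the maximal tail density), pore axis
`"auto"` = the 0.2 nm grid column maximizing the core polar count (ties
break to the first grid point, deterministically).  Once
$\xi_\mathrm{chain} \ge 1 - \varepsilon$ (branch threshold
$\varepsilon = 0.01$), `xi_pore()` switches to
$\max(1, \hat R/R_0)$ with $\hat R = \sqrt{N_p \bar v / (\pi h)}$, the
radius of a water-filled cylinder holding the $N_p$ core polar particles
at one particle per $\bar v = 0.030\,$nm³.  The clamp at 1 makes the
branches join continuously: a bare water wire has $\hat R < R_0$ and
reports exactly 1.

The ramp is deliberately non-smooth: this package analyses states rather
than biasing dynamics, so the differentiable switching functions used to
drive sampling are unnecessary.

# PMF estimators

* **Anchoring.**  Profiles are measured from the flat-membrane baseline,
  the minimum of $G$ over $\xi_p < 0.5$.  For noisy profiles the pointwise
  minimum is biased low by extreme-value selection, so the baseline is the
  minimum of a smoothing fit to the nucleation branch instead; for
  noise-free data (detected by a second-difference noise estimate) the raw
  minimum is used, keeping the anchoring exact.  Profiles with no points
  below $\xi_p = 0.5$ are treated as pre-anchored.
* **$\Delta G_\mathrm{nuc}$** is linear interpolation of $G$ at
  $\xi_p = 0.92$.  Linear (not spline) interpolation cannot overshoot on
  the steep nucleation rise.
* **$\gamma$** is the OLS slope of $G$ vs $R = \xi_p R_0$ over
  $4 \le \xi_p \le 6.5$, divided by $2\pi$ and converted with
  1 kJ mol⁻¹ nm⁻¹ = 1.66054 pN.  The $2\pi$ follows from
  $\mathrm{d}\Delta G_\mathrm{CNT}/\mathrm{d}R = 2\pi\gamma$; a
  `slope_is_gamma` toggle reports the raw slope for comparison with
  conventions that identify the slope itself with the line tension.
  $r^2 < 0.9$ sets a diagnostic flag instead of raising an error.
* **Metastability.**  `detect_metastable()` searches $\xi_p > 1$ for local
  minima whose depth to the lower flanking maximum reaches
  $\max(\text{min\_depth}, 2\,\mathrm{SE})$ (default floor 1 kJ/mol).
  Noisy profiles are first denoised with a centred running mean of
  half-width 0.35 coordinate units.  The running mean is chosen over a
  smoothing spline because it preserves monotonicity exactly: it cannot
  fabricate a local minimum from lack of fit at the sharp
  plateau-to-linear crossover, a failure mode we observed for splines at
  both low and high equivalent degrees of freedom.
* **Bootstrap errors.**  With $\ge 3$ replicate profiles, a case bootstrap
  over replicates.  With a single profile, a residual bootstrap: trend
  from a short (5-point) running mean, residuals recentred and rescaled so
  their spread matches a robust second-difference noise estimate — the
  rescaling keeps the resampled noise honest whether the trend under- or
  over-fits.  The resulting $\gamma$ SE matches the closed-form OLS slope
  SE on synthetic data (tested), and both estimators recover their ground
  truth within 2 SE at the expected ~95% rate (tested over 100 seeds at
  2 kJ/mol noise).
* **Hysteresis** is the maximal absolute gap between two anchored
  profiles over their common range, with linear interpolation across
  mismatched grids.

# Continuum stage

`hkh_energy()` integrates the HKH density over explicit quadrature nodes
(`dA`, $\tilde H$, $\tilde K_G$, $t$); with $t \equiv 0$ and
$\bar\kappa = 0$ it reduces to the plain Helfrich functional (tested
against an independent implementation at $10^{-10}$ relative).  Published
tilt moduli are often tabulated per bilayer while the functional is
written per monolayer; the value is used verbatim and a `leaflet_factor`
argument (default 1) lets users apply 0.5 explicitly rather than having a
convention injected silently.  $\bar\kappa$ defaults to 0: pore formation
changes membrane topology so the Gaussian term is retained as an option,
but no reliable values are available to default to.

`rim_quadrature_line_tension()` integrates the bending density over the
half-torus rim with the exact area element and, by default, the same
curvature model as the closed form (tube curvature $2/d_{hc}$, in-plane
curvature zero).  Its only finite-size deviation is then the area element,
a relative excess $(\pi - 2) d_{hc}/(2\pi R_p)$ (≈ 0.2% at
$R_p = 100\,d_{hc}$), so it converges cleanly to
$\gamma^\mathrm{bend}_\mathrm{Helf}$.  Setting
`include_azimuthal = TRUE` adds the true torus in-plane curvature
$-\cos\theta/\rho$; this probes corrections beyond the wide-pore model and
deviates from the closed form by $\mathcal{O}(1/R_p)$ terms that reach
~1% at $R_p = 100\,d_{hc}$ for strongly curved lipids.

Area rescaling and probabilities are evaluated in log space
($k_B = 0.00831446$ kJ mol⁻¹ K⁻¹), so extremely stable membranes cannot
underflow the reported floor-log10 order.  The package default temperature
is 310 K (physiological); note that order-of-magnitude statements can
shift by one decade between 298 K and 310 K for large barriers, which is
why the temperature is an explicit argument everywhere.

# Moduli estimators

Tilt vectors follow $t = d/(n\cdot d) - n$ with the director $d$ from the
tail-bead centroid to the head bead and planar reference normals
$n = \pm\hat z$ per leaflet — global normals are appropriate because the
estimators are defined for planar membranes.  Lipids with
$n \cdot d \le 0.1$ (nearly in-plane) are excluded and counted.  The
quadratic-fluctuation estimators

$$\kappa_\theta = \frac{k_B T}{\mathrm{var_{pc}}(t)\, A_l}, \qquad
  \kappa = \frac{k_B T}{\mathrm{var}(S)\, A_l}$$

are used instead of fitting $-k_BT \ln P(t)$: for Gaussian fluctuations
they are identical and need no binning choices.  Pair splay uses in-plane
neighbour separations of 0.5–1.0 nm.  Spontaneous curvature comes from the
first moment of a tabulated lateral stress profile about the leaflet
pivot, $J_s = \kappa^{-1}\int (z - z_0)\, s(z)\, \mathrm{d}z$ by
trapezoidal quadrature, with the sign convention positive = curving
towards the head groups; the pivot defaults to the profile's stored pivot
(the generator's mid-leaflet plane) and is flagged as
convention-dependent.  Hydrophobic thickness is the distance between the
two crossings of the plateau-normalized tail and water density histograms
(0.1 nm bins, linear interpolation between bin centres).

# What the synthetic generator emulates — and what it does not

The generator produces every input with known ground truth:

* **Frames** are coarse placeholders (1 head + 2 tail beads per lipid,
  discrete water beads at 33.3 nm⁻³, jittered lattices): correct roles,
  geometry, periodicity and species bookkeeping, but no thermal
  fluctuations, no realistic lipid shape, no correlations.  Passing tests
  therefore validate geometry and bookkeeping of the estimators, not their
  statistical behaviour on thermalized configurations.
* **Tilt/splay samples** are exactly Gaussian — they validate estimator
  inversion, not the Gaussianity assumption itself.
* **Stress profiles** are smooth analytic shapes whose leaflet moment is
  exact by construction.
* **PMFs** have the canonical shape (smoothstep rise reaching
  $\Delta G_\mathrm{nuc}$ exactly at $\xi_p = 0.92$, plateau, monotone
  Hermite crossover on $[3, 3.5]$, exactly linear tail of slope
  $2\pi\gamma R_0$) plus an optional compact cosine-squared metastable
  well at $\xi_p = 2.5$ (half-width 1, so the tail at $\xi_p \ge 3.5$
  stays exactly linear).  Noise is i.i.d. Gaussian per grid point, added
  after the noise-free curve is anchored; real umbrella-sampling errors
  are correlated across windows, so the bootstrap here is validated by
  parameter recovery, not by mimicking the real error structure.  The
  default point noise is 0.5 kJ/mol — published profiles are smooth and
  their visible point scatter is well below the ~1–2 kJ/mol errors of
  derived quantities — while round-trip studies use 2 kJ/mol to stress the
  estimators.

Species counts use largest-remainder rounding (deterministic, sums
exactly; remainder ties break by input order).  Every generator is
bit-reproducible under a fixed seed, implemented without disturbing the
caller's RNG state.

Rim lipids in pore fixtures are placed at the bulk area per lipid, so rim
and bulk densities are comparable and the sign of enrichment − 1 is
meaningful.  The *absolute* rim enrichment of a species still carries a
common rim-geometry factor; the ratio of two species' enrichments removes
it exactly, which is how the tests recover the generator's factors
quantitatively.

# Problem sizes and runtime choices

The test-suite study sizes are: 100-seed PMF round trips at 2 kJ/mol
noise with 200 bootstrap draws; 50-seed metastability classification;
moduli recovery at $10^5$ samples (20 parameter draws × 10 seeds,
median); sorting recovery on 50 fixtures of 50 frames × 400 lipids.
These sizes put the statistical errors of each estimator an order of
magnitude below the tested tolerances while keeping the whole suite in
the minutes range on a single core.

# Known limitations

* No umbrella sampling, WHAM/MBAR, or free-energy estimation from
  trajectories: profiles are inputs (XVG-compatible or CSV text).
* No local stress-tensor computation: stress profiles are inputs.
* No variational minimization of the HKH functional with tilt boundary
  conditions; the simple rim integration is known to overestimate line
  tensions substantially, which is why it serves as a correlate rather
  than a quantitative predictor.
* Planar reference normals only; curved-frame director analysis is out of
  scope.
* The toy frames do not drift, undulate, or flip-flop; time-resolved
  sorting is out of scope.
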