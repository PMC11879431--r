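#' Elastic parameter tables
#'
#' Per-membrane continuum parameters: spontaneous curvature `J_s` (nm^-1),
#' monolayer bending modulus `kappa` (kJ/mol), tilt modulus `kappa_theta`
#' (kJ mol^-1 nm^-2), optional Gaussian modulus `kappa_bar` (kJ/mol,
#' default 0), hydrophobic thickness `d_hc` (nm) and area per lipid
#' `area_per_lipid` (nm^2).
#'
#' @param label Membrane name(s).
#' @param J_s Spontaneous curvature (nm^-1).
#' @param kappa Monolayer bending modulus (kJ/mol, > 0).
#' @param kappa_theta Tilt modulus (kJ mol^-1 nm^-2, > 0).
#' @param kappa_bar Gaussian modulus (kJ/mol).
#' @param d_hc Hydrophobic thickness (nm), in (1.5, 5) when given.
#' @param area_per_lipid Area per lipid (nm^2, > 0) when given.
#' @return An `elastic_parameters` tibble (one row per membrane).
#' @export
elastic_parameters <- function(label, J_s, kappa, kappa_theta, kappa_bar = 0,
                               d_hc = NA_real_, area_per_lipid = NA_real_) {
  d <- tibble(label = label, J_s = J_s, kappa = kappa,
              kappa_theta = kappa_theta, kappa_bar = kappa_bar,
              d_hc = d_hc, area_per_lipid = area_per_lipid)
  if (any(d$kappa <= 0) || any(d$kappa_theta <= 0)) {
    abort("`kappa` and `kappa_theta` must be > 0.",
          class = "poremech_validation_error")
  }
  if (any(!is.na(d$d_hc) & (d$d_hc <= 1.5 | d$d_hc >= 5))) {
    abort("`d_hc` must lie in (1.5, 5) nm.", class = "poremech_validation_error")
  }
  if (any(!is.na(d$area_per_lipid) & d$area_per_lipid <= 0)) {
    abort("`area_per_lipid` must be > 0.", class = "poremech_validation_error")
  }
  tibble::new_tibble(d, class = "elastic_parameters")
}

#' Reference elastic moduli for palmitoyl-oleoyl model membranes
#'
#' Published spontaneous curvatures, monolayer bending moduli and bilayer
#' tilt moduli for nine single-component or binary palmitoyl-oleoyl (PO)
#' model membranes, estimated from equilibrium simulations of planar
#' membranes, together with the rim line tension estimated from bending
#' elasticity (`gamma_helf_pn`).  These values serve as realistic inputs
#' and ground truth ranges for the moduli estimators and the continuum
#' stage; hydrophobic thicknesses are not part of the published table and
#' are left `NA`.
#'
#' @return A tibble with columns `label`, `J_s`, `J_s_se` (nm^-1), `kappa`,
#'   `kappa_se` (kJ/mol), `kappa_theta`, `kappa_theta_se`
#'   (kJ mol^-1 nm^-2), `gamma_helf_pn`, `gamma_helf_se` (pN).
#' @export
reference_elastic_parameters <- function() {
  tibble::tribble(
    ~label,                 ~J_s,    ~J_s_se, ~kappa, ~kappa_se, ~kappa_theta, ~kappa_theta_se, ~gamma_helf_pn, ~gamma_helf_se,
    "POPC",                 -0.001,  0.028,   33.7,   1.4,       42.53,        1.7,             62,             4,
    "POPE",                 -0.178,  0.005,   48.0,   0.9,       65.6,         2.9,             130,            3,
    "POPA",                  0.027,  0.006,   53.1,   2.3,       72.1,         2.7,             86,             4,
    "POPI",                  0.172,  0.016,   42.8,   2.1,       55.8,         2.6,             44,             3,
    "POPG",                  0.227,  0.017,   30.2,   1.3,       35.8,         1.6,             32,             2,
    "POPS",                 -0.019,  0.007,   50.3,   2.3,       78,           4,               91,             5,
    "POPC:LPC 80:20",        0.085,  0.008,   28.2,   1.2,       32.6,         1.4,             43,             2,
    "POPC:OA 80:20",        -0.063,  0.009,   37.7,   1.5,       58.8,         2.5,             81,             4,
    "POPC:CHOL 70:30",      -0.0007, 0.003,   105,    5,         166,          8,               160,            8
  )
}

#' Helfrich-Kozlov-Hamm elastic energy of a monolayer patch
#'
#' Quadrature of the monolayer deformation energy density
#' \deqn{f = \frac{\kappa}{2}(\tilde H - J_s)^2 +
#'           \frac{\kappa_\theta}{2} t^2 + \bar\kappa \tilde K_G}
#' over a discretized surface, where \eqn{\tilde H} is the director mean
#' curvature (sum of principal curvatures), \eqn{t} the tilt magnitude and
#' \eqn{\tilde K_G} the Gaussian curvature.  With `tilt = 0` and
#' `kappa_bar = 0` this reduces to the plain Helfrich bending energy.
#'
#' The tilt modulus is applied verbatim; published tables often quote a
#' bilayer tilt modulus while the functional is written per monolayer, so
#' `leaflet_factor` (default 1) lets callers rescale the tilt term (e.g.
#' 0.5) without silently injecting a convention.
#'
#' @param surface A tibble of quadrature nodes with columns `dA` (area
#'   element, nm^2, > 0), `H` (director mean curvature, nm^-1), `K_G`
#'   (Gaussian curvature, nm^-2) and `tilt` (tilt magnitude,
#'   dimensionless); see [flat_patch()] and [spherical_cap_surface()].
#' @param kappa Bending modulus (kJ/mol).
#' @param J_s Spontaneous curvature (nm^-1).
#' @param kappa_theta Tilt modulus (kJ mol^-1 nm^-2).
#' @param kappa_bar Gaussian modulus (kJ/mol).
#' @param leaflet_factor Multiplier applied to the tilt term.
#' @return Elastic energy in kJ/mol.
#' @examples
#' hkh_energy(spherical_cap_surface(radius = 10, area = 100), kappa = 33.7)
#' @export
hkh_energy <- function(surface, kappa, J_s = 0, kappa_theta = 0,
                       kappa_bar = 0, leaflet_factor = 1) {
  required <- c("dA", "H", "K_G", "tilt")
  missing <- setdiff(required, names(surface))
  if (length(missing) > 0) {
    abort(paste0("surface is missing columns: ", paste(missing, collapse = ", ")),
          class = "poremech_validation_error")
  }
  if (nrow(surface) < 16 || any(surface$dA <= 0)) {
    abort("surface needs >= 16 nodes with positive area elements.",
          class = "poremech_validation_error")
  }
  dens <- kappa / 2 * (surface$H - J_s)^2 +
    leaflet_factor * kappa_theta / 2 * surface$tilt^2 +
    kappa_bar * surface$K_G
  sum(surface$dA * dens)
}

#' Simple quadrature surfaces
#'
#' Node constructors for [hkh_energy()]: a flat patch of given total area
#' (optionally with uniform tilt) and a spherical cap of given radius and
#' area (mean curvature `2/radius`, Gaussian curvature `1/radius^2`).
#'
#' @param area Total patch area (nm^2).
#' @param n Number of quadrature nodes (>= 16).
#' @param tilt Uniform tilt magnitude.
#' @param radius Sphere radius (nm).
#' @return A tibble of quadrature nodes (`dA`, `H`, `K_G`, `tilt`).
#' @export
flat_patch <- function(area, n = 64, tilt = 0) {
  tibble(dA = rep(area / n, n), H = 0, K_G = 0, tilt = tilt)
}

#' @rdname flat_patch
#' @export
spherical_cap_surface <- function(radius, area, n = 64, tilt = 0) {
  tibble(dA = rep(area / n, n), H = 2 / radius, K_G = 1 / radius^2,
         tilt = tilt)
}

#' Closed-form rim line tension from bending elasticity
#'
#' The bending energy per unit rim length of a wide toroidal pore, obtained
#' by integrating the bending term of the monolayer elastic energy over the
#' rim with one principal curvature fixed at `2/d_hc` (the monolayer
#' wrapping the half-torus tube of radius `d_hc/2`) and the in-plane
#' principal curvature taken as zero for a large pore:
#' \deqn{\gamma^{bend}_{Helf} = \kappa d_{hc} \frac{\pi}{4}
#'       \left(\frac{2}{d_{hc}} - J_s\right)^2.}
#' A spontaneous curvature matching the rim curvature (`J_s = 2/d_hc`)
#' yields zero; lipids with positive intrinsic curvature lower the rim
#' penalty.
#'
#' @param kappa Monolayer bending modulus (kJ/mol).  Vectorized over all
#'   parameters.
#' @param d_hc Hydrophobic thickness (nm, > 0).
#' @param J_s Spontaneous curvature (nm^-1).
#' @return Line tension in pN.
#' @examples
#' helfrich_line_tension(33.7, 2.85)  # ~62 pN
#' @export
helfrich_line_tension <- function(kappa, d_hc, J_s = 0) {
  if (any(d_hc <= 0)) {
    abort("`d_hc` must be > 0.", class = "poremech_validation_error")
  }
  kj_mol_nm_to_pn(kappa * d_hc * pi / 4 * (2 / d_hc - J_s)^2)
}

#' Rim line tension by numerical quadrature over the torus rim
#'
#' Numerically integrates the bending energy density over the semicircular
#' rim cross-section (a half-torus of tube radius `d_hc/2` whose waist sits
#' at `pore_radius`) with the exact torus area element, and divides by the
#' rim length `2 pi pore_radius`.  By default the curvature model is the
#' same as in [helfrich_line_tension()] (tube curvature `2/d_hc`, in-plane
#' principal curvature zero), so the quadrature converges to the closed
#' form as `pore_radius` grows; the only finite-size effect is the area
#' element, a relative excess of \eqn{(\pi-2) d_{hc} / (2\pi R_p)}.  With
#' `include_azimuthal = TRUE` the true torus azimuthal curvature
#' `-cos(theta)/rho` is added to the mean curvature to probe finite-size
#' corrections beyond the closed-form model.
#'
#' @inheritParams helfrich_line_tension
#' @param pore_radius Pore waist radius (nm), >= `d_hc`.
#' @param n_nodes Number of quadrature nodes over the cross-section.
#' @param include_azimuthal Include the in-plane torus curvature.
#' @return Line tension in pN.
#' @export
rim_quadrature_line_tension <- function(kappa, d_hc, J_s = 0, pore_radius,
                                        n_nodes = 4001,
                                        include_azimuthal = FALSE) {
  stopifnot_scalar_number(d_hc, "d_hc", min = 1e-9)
  stopifnot_scalar_number(pore_radius, "pore_radius", min = d_hc)
  a <- d_hc / 2
  r_c <- pore_radius + a
  dth <- pi / n_nodes
  theta <- seq(-pi / 2 + dth / 2, pi / 2 - dth / 2, length.out = n_nodes)
  rho <- r_c - a * cos(theta)
  H <- 2 / d_hc + if (include_azimuthal) -cos(theta) / rho else 0
  energy_per_phi <- sum(kappa / 2 * (H - J_s)^2 * a * rho * dth)  # per radian
  kj_mol_nm_to_pn(energy_per_phi * 2 * pi / (2 * pi * pore_radius))
}

#' Classical nucleation theory pore energy
#'
#' Free energy of an open pore of radius `R` under rim line tension `gamma`
#' and lateral membrane tension `sigma`:
#' \deqn{\Delta G_{CNT}(R) = 2\pi R \gamma - \pi R^2 \sigma,} converted
#' from pN nm to kJ/mol.  With `sigma > 0` the barrier top sits at
#' `R* = gamma / sigma`.
#'
#' @param R Pore radius (nm, >= 0).  Vectorized.
#' @param gamma Line tension (pN).
#' @param sigma Lateral tension (pN/nm).
#' @return Energy in kJ/mol.
#' @examples
#' cnt_energy(1, 40)  # ~151 kJ/mol
#' @export
cnt_energy <- function(R, gamma, sigma = 0) {
  if (any(R < 0)) abort("`R` must be >= 0.", class = "poremech_validation_error")
  (2 * pi * R * gamma - pi * R^2 * sigma) * .kJ_mol_per_pN_nm
}

#' Rescale a nucleation free energy to a different membrane area
#'
#' The probability of spontaneous pore nucleation is proportional to the
#' membrane area, so a nucleation free energy obtained in a small patch of
#' area `area_sim` translates to an effective free energy in a larger
#' membrane of area `area_exp`:
#' \deqn{\Delta G^{exp}_{nuc} = \Delta G_{nuc} -
#'       k_B T \ln(A_{exp}/A_{sim}).}
#'
#' @param dG Nucleation free energy (kJ/mol) in the reference patch.
#' @param area_exp,area_sim Membrane areas (> 0, same units).
#' @param temperature Temperature (K).
#' @return Rescaled free energy (kJ/mol).
#' @examples
#' rescale_nucleation_energy(90, 1e9, 83)  # ~48 kJ/mol
#' @export
rescale_nucleation_energy <- function(dG, area_exp, area_sim,
                                      temperature = 310) {
  if (any(area_exp <= 0) || any(area_sim <= 0)) {
    abort("areas must be > 0.", class = "poremech_validation_error")
  }
  ctx <- thermo_context(temperature)
  dG - ctx$kT * log(area_exp / area_sim)
}

#' Spontaneous pore probability and its order of magnitude
#'
#' Boltzmann probability of finding an open pore across a membrane with
#' nucleation free energy `dG`, \eqn{P \approx \exp(-\Delta G / k_B T)},
#' together with its decimal order `floor(log10 P)`.  Computed in log space
#' so very stable membranes do not underflow.
#'
#' @param dG Nucleation free energy (kJ/mol).  Vectorized.
#' @param temperature Temperature (K).
#' @return A tibble with columns `dG`, `probability`, `order`.
#' @examples
#' pore_probability(48)   # ~8e-9, order -9
#' @export
pore_probability <- function(dG, temperature = 310) {
  ctx <- thermo_context(temperature)
  log10p <- -dG / (ctx$kT * log(10))
  tibble(dG = dG, probability = 10^log10p, order = floor(log10p))
}

#' Pore-probability ratio between two membranes
#'
#' A membrane whose nucleation barrier is higher by `ddG` suppresses pores
#' by the Boltzmann factor \eqn{\exp(\Delta\Delta G / k_B T)}.
#'
#' @param ddG Barrier difference (kJ/mol).  Vectorized.
#' @param temperature Temperature (K).
#' @return A tibble with columns `ddG`, `factor`, `order`
#'   (`floor(log10 factor)`).
#' @examples
#' stability_factor(80)  # ~3e13, order 13
#' @export
stability_factor <- function(ddG, temperature = 310) {
  ctx <- thermo_context(temperature)
  log10f <- ddG / (ctx$kT * log(10))
  tibble(ddG = ddG, factor = 10^log10f, order = floor(log10f))
}

#' Correlate two membrane properties with labelled exclusions
#'
#' Pearson correlation and ordinary-least-squares line between two labelled
#' vectors of per-membrane quantities, excluding named membranes from the
#' regression (used e.g. to leave out a membrane whose key component is
#' laterally depleted from the pore rim and therefore off-trend).
#'
#' @param data A data frame of per-membrane values.
#' @param x,y Column names (tidy-eval) to correlate.
#' @param label Column identifying membranes (tidy-eval); required when
#'   `exclude` is used.
#' @param exclude Character vector of labels to drop.
#' @return A one-row tibble: `r`, `slope`, `intercept`, `n`, `excluded`
#'   (list column).
#' @examples
#' correlate_membranes(reference_elastic_parameters(),
#'                     kappa, gamma_helf_pn, label = label,
#'                     exclude = "POPC:CHOL 70:30")
#' @export
correlate_membranes <- function(data, x, y, label = NULL, exclude = NULL) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  lq <- rlang::enquo(label)
  lv <- if (rlang::quo_is_null(lq)) rep(NA_character_, length(xv))
        else as.character(rlang::eval_tidy(lq, data))
  keep <- rep(TRUE, length(xv))
  if (!is.null(exclude)) {
    if (all(is.na(lv))) {
      abort("`label` is required when `exclude` is used.",
            class = "poremech_validation_error")
    }
    keep <- !(lv %in% exclude)
  }
  keep <- keep & is.finite(xv) & is.finite(yv)
  if (sum(keep) < 3) {
    abort("need >= 3 retained (x, y) pairs.", class = "poremech_validation_error")
  }
  fit <- lm(yv[keep] ~ xv[keep])
  tibble(
    r = cor(xv[keep], yv[keep]),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n = sum(keep),
    excluded = list(exclude %||% character(0))
  )
}
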