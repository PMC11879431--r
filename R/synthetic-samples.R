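#' Boltzmann-sample lipid tilt vectors with known tilt modulus
#'
#' Draws i.i.d. two-component tilt vectors from the quadratic tilt energy
#' per lipid, \eqn{(1/2) \kappa_\theta A_l |t|^2}, so that each component is
#' Gaussian with variance \eqn{k_B T / (\kappa_\theta A_l)}.  These samples
#' are the ground-truth input for validating the fluctuation-based tilt
#' modulus estimator.
#'
#' @param kappa_theta Tilt modulus in kJ mol^-1 nm^-2 (> 0).
#' @param area_per_lipid Area per lipid in nm^2, in (0.3, 1.5).
#' @param n_samples Number of vectors (>= 100).
#' @param temperature Temperature in K.
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `tx`, `ty` and attributes
#'   `area_per_lipid`, `temperature`, `kappa_theta_true`.
#' @examples
#' t <- sample_tilt_vectors(42.53, 0.64, 1e4, seed = 1)
#' var(t$tx)  # ~ kT / (kappa_theta * A_l)
#' @export
sample_tilt_vectors <- function(kappa_theta, area_per_lipid, n_samples,
                                temperature = 310, seed = NULL) {
  validate_director_spec(kappa_theta, area_per_lipid, n_samples, temperature)
  s <- sqrt(.kB * temperature / (kappa_theta * area_per_lipid))
  out <- with_seed(seed, tibble(tx = rnorm(n_samples, 0, s),
                                ty = rnorm(n_samples, 0, s)))
  attr(out, "area_per_lipid") <- area_per_lipid
  attr(out, "temperature") <- temperature
  attr(out, "kappa_theta_true") <- kappa_theta
  out
}

#' Boltzmann-sample monolayer splay values with known bending modulus
#'
#' Draws i.i.d. scalar splay samples (director divergence, the curvature
#' seen by the bending term of the monolayer elastic energy) from a Gaussian
#' centred at the spontaneous curvature `J_s` with variance
#' \eqn{k_B T / (\kappa A_l)}.
#'
#' @param kappa Monolayer bending modulus in kJ/mol (> 0).
#' @param area_per_lipid Area per lipid in nm^2, in (0.3, 1.5).
#' @param n_samples Number of samples (>= 100).
#' @param J_s Spontaneous curvature in nm^-1 (the sample mean).
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @return Numeric vector of splay values (nm^-1) with attributes
#'   `area_per_lipid`, `temperature`, `kappa_true`, `J_s_true`.
#' @export
sample_splay_values <- function(kappa, area_per_lipid, n_samples, J_s = 0,
                                temperature = 310, seed = NULL) {
  validate_director_spec(kappa, area_per_lipid, n_samples, temperature)
  s <- sqrt(.kB * temperature / (kappa * area_per_lipid))
  out <- with_seed(seed, rnorm(n_samples, J_s, s))
  attr(out, "area_per_lipid") <- area_per_lipid
  attr(out, "temperature") <- temperature
  attr(out, "kappa_true") <- kappa
  attr(out, "J_s_true") <- J_s
  out
}

validate_director_spec <- function(modulus, area_per_lipid, n_samples,
                                   temperature) {
  stopifnot_scalar_number(modulus, "modulus", min = 1e-12)
  if (area_per_lipid <= 0.3 || area_per_lipid >= 1.5) {
    abort("`area_per_lipid` must lie in (0.3, 1.5) nm^2.",
          class = "poremech_validation_error")
  }
  stopifnot_scalar_number(n_samples, "n_samples", min = 100)
  stopifnot_scalar_number(temperature, "temperature", min = 250, max = 400)
  invisible(TRUE)
}

#' Analytic lateral stress profile with known first moment
#'
#' Constructs a mirror-symmetric bilayer stress density \eqn{s(z)} whose
#' first moment over the upper leaflet about the leaflet pivot equals
#' \eqn{\kappa J_s} exactly, enabling recovery tests for the stress-profile
#' route to the spontaneous curvature.  The upper leaflet spans
#' `[0, max(grid)]` with pivot at its midpoint; the lower leaflet is the
#' mirror image, so the torque integrand \eqn{(z - p)\,s(z)} is
#' antisymmetric across the midplane and both leaflets carry the same
#' spontaneous-curvature torque under the leaflet-oriented sign convention
#' of [spontaneous_curvature()].
#'
#' The shape is \eqn{s(z) \propto (z - p)\cos^2(\pi (z - p)/L)} with
#' \eqn{p = L/2}; its moment about `p` is
#' \eqn{L^3 (1/24 - 1/(4\pi^2))} per unit amplitude, which fixes the
#' amplitude analytically.
#'
#' @param J_s Spontaneous curvature (nm^-1) encoded in the profile.
#' @param kappa Monolayer bending modulus (kJ/mol) used in the encoding.
#' @param d_hc Hydrophobic thickness (nm), stored as metadata.
#' @param grid Symmetric z grid about 0 with spacing <= 0.05 nm; defaults to
#'   `seq(-d_hc, d_hc, by = 0.025)`.
#' @return A `stress_profile`: tibble with columns `z` (nm) and `s`
#'   (kJ mol^-1 nm^-3), with attributes `leaflet_bounds`, `pivot`, `d_hc`.
#' @examples
#' sp <- make_stress_profile(J_s = 0.172, kappa = 42.8, d_hc = 2.85)
#' spontaneous_curvature(sp, kappa = 42.8)  # ~0.172
#' @export
make_stress_profile <- function(J_s, kappa, d_hc = 2.8, grid = NULL) {
  stopifnot_scalar_number(kappa, "kappa", min = 1e-12)
  stopifnot_scalar_number(d_hc, "d_hc", min = 1e-6)
  if (is.null(grid)) grid <- seq(-d_hc, d_hc, by = 0.025)
  grid <- sort(grid)
  if (max(abs(grid + rev(grid))) > 1e-9) {
    abort("`grid` must be symmetric about 0.", class = "poremech_validation_error")
  }
  if (max(diff(grid)) > 0.05 + 1e-12) {
    abort("`grid` spacing must be <= 0.05 nm.", class = "poremech_validation_error")
  }
  L <- max(grid)
  p <- L / 2
  m0 <- L^3 * (1 / 24 - 1 / (4 * pi^2))  # moment of the unit shape about p
  alpha <- kappa * J_s / m0
  shape <- function(z) alpha * (z - p) * cos(pi * (z - p) / L)^2
  s <- numeric(length(grid))
  up <- grid >= 0
  s[up] <- shape(grid[up])
  s[!up] <- shape(-grid[!up])
  out <- tibble::new_tibble(tibble(z = grid, s = s), class = "stress_profile")
  attr(out, "leaflet_bounds") <- list(upper = c(0, L), lower = c(-L, 0))
  attr(out, "pivot") <- p
  attr(out, "d_hc") <- d_hc
  out
}
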