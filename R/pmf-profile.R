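#' PMF profiles
#'
#' A `pmf_profile` is a tibble holding a one-dimensional free-energy profile
#' along the pore coordinate: columns `xi` (dimensionless, strictly
#' increasing), `G` (kJ/mol) and optionally `se` (per-point standard error,
#' kJ/mol).  The nucleated-pore radius `R0` (nm) that sets the length scale
#' of the expansion branch (`R = xi * R0`) is stored as an attribute.
#'
#' @param xi Strictly increasing coordinate grid.
#' @param G Free energy in kJ/mol.
#' @param se Optional per-point standard error in kJ/mol.
#' @param R0 Nucleated-pore radius in nm (default 0.4).
#' @return A `pmf_profile` tibble.
#' @export
pmf_profile <- function(xi, G, se = NULL, R0 = 0.4) {
  if (length(xi) != length(G)) {
    abort("`xi` and `G` must have the same length.",
          class = "poremech_validation_error")
  }
  if (any(!is.finite(xi)) || any(!is.finite(G))) {
    abort("`xi` and `G` must be finite.", class = "poremech_validation_error")
  }
  if (any(diff(xi) <= 0)) {
    abort("`xi` must be strictly increasing.",
          class = "poremech_validation_error")
  }
  stopifnot_scalar_number(R0, "R0", min = 1e-9)
  d <- tibble(xi = as.numeric(xi), G = as.numeric(G))
  if (!is.null(se)) {
    if (length(se) != length(xi) || any(se < 0)) {
      abort("`se` must be non-negative and match `xi` in length.",
            class = "poremech_validation_error")
    }
    d$se <- as.numeric(se)
  }
  out <- tibble::new_tibble(d, R0 = R0, class = "pmf_profile")
  out
}

#' @rdname pmf_profile
#' @param x An object.
#' @export
is_pmf_profile <- function(x) inherits(x, "pmf_profile")

pmf_R0 <- function(pmf) attr(pmf, "R0") %||% 0.4

# smoothstep: 0 at t<=0, 1 at t>=1, C1
.smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t^2 * (3 - 2 * t)
}

#' Generate a synthetic pore-formation PMF with known ground truth
#'
#' Builds a free-energy profile with the canonical shape of pore nucleation
#' and expansion: a steep sigmoidal rise reaching exactly `dG_nuc_true` at
#' `xi = 0.92` (the thin-water-wire state), a plateau over the toroidal-pore
#' region, a smooth crossover, and an exactly linear tail for `xi >= 3.5`
#' with slope \eqn{2\pi \gamma R_0} (converted from pN to kJ/mol per
#' coordinate unit) encoding the rim line tension.  An optional metastable
#' dip (a compact, C1 cosine-squared well of depth `metastable_depth`,
#' half-width 1 coordinate unit, centred at `xi = 2.5`) emulates membranes
#' that form long-lived open pores.  I.i.d. Gaussian noise of standard
#' deviation `noise_sd` is added after the noise-free curve is anchored at
#' zero in its `xi < 0.5` minimum; when `noise_sd > 0` the per-point `se`
#' column is set to `noise_sd`.
#'
#' @param gamma_true Rim line tension in pN (>= 0).
#' @param dG_nuc_true Nucleation free energy in kJ/mol.
#' @param R0 Nucleated-pore radius in nm.
#' @param metastable_depth Depth of the metastable well in kJ/mol (0 = none).
#' @param noise_sd Standard deviation of the additive point noise (kJ/mol).
#' @param xi_grid Strictly increasing grid spanning at least `[0.2, 6.5]`;
#'   the default includes the nucleation point 0.92 as a grid node.
#' @param seed Integer seed for the noise.
#' @return A [pmf_profile()] with attributes recording the ground truth.
#' @examples
#' pmf <- make_synthetic_pmf(40, 90, noise_sd = 0)
#' nucleation_free_energy(pmf)      # 90
#' line_tension(pmf)$gamma_pn       # 40
#' @export
make_synthetic_pmf <- function(gamma_true, dG_nuc_true, R0 = 0.4,
                               metastable_depth = 0, noise_sd = 0.5,
                               xi_grid = sort(c(seq(0.2, 6.5, by = 0.05), 0.92)),
                               seed = NULL) {
  stopifnot_scalar_number(gamma_true, "gamma_true", min = 0)
  stopifnot_scalar_number(dG_nuc_true, "dG_nuc_true")
  stopifnot_scalar_number(R0, "R0", min = 1e-9)
  stopifnot_scalar_number(metastable_depth, "metastable_depth", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  xi <- sort(as.numeric(xi_grid))
  if (any(diff(xi) <= 0)) {
    abort("`xi_grid` must be strictly increasing.",
          class = "poremech_validation_error")
  }
  if (xi[1] > 0.2 + 1e-9 || xi[length(xi)] < 6.5 - 1e-9) {
    abort("`xi_grid` must span at least [0.2, 6.5].",
          class = "poremech_validation_error")
  }

  slope <- 2 * pi * pn_to_kj_mol_nm(gamma_true) * R0  # kJ/mol per xi unit
  G <- synthetic_pmf_shape(xi, dG_nuc_true, slope, metastable_depth)
  # noise-free curve is already zero at its xi < 0.5 minimum by construction
  se <- NULL
  if (noise_sd > 0) {
    G <- G + with_seed(seed, rnorm(length(xi), 0, noise_sd))
    se <- rep(noise_sd, length(xi))
  }
  out <- pmf_profile(xi, G, se = se, R0 = R0)
  attr(out, "gamma_true") <- gamma_true
  attr(out, "dG_nuc_true") <- dG_nuc_true
  attr(out, "metastable_depth") <- metastable_depth
  attr(out, "noise_sd") <- noise_sd
  out
}

# Noise-free PMF shape: smoothstep rise on [0.2, 0.92], flat plateau to 3.0,
# Hermite crossover on [3.0, 3.5] (end slopes 0 and `slope`, monotone),
# exactly linear beyond 3.5, plus a compact cosine-squared well at 2.5.
synthetic_pmf_shape <- function(xi, dG, slope, depth) {
  G <- numeric(length(xi))
  rise <- xi <= 0.92
  G[rise] <- dG * .smoothstep((xi[rise] - 0.2) / (0.92 - 0.2))
  plateau <- xi > 0.92 & xi <= 3.0
  G[plateau] <- dG
  cross <- xi > 3.0 & xi < 3.5
  if (any(cross)) {
    t <- (xi[cross] - 3.0) / 0.5
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    G[cross] <- h00 * dG + h01 * (dG + slope * 0.25) + h11 * 0.5 * slope
    # h10 term carries slope 0 at the left end
  }
  lin <- xi >= 3.5
  G[lin] <- dG + slope * 0.25 + slope * (xi[lin] - 3.5)
  if (depth > 0) {
    u <- xi - 2.5
    inside <- abs(u) < 1
    G[inside] <- G[inside] - depth * cos(pi * u[inside] / 2)^2
  }
  G
}
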