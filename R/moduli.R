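#' Lipid director and tilt-vector field of a planar frame
#'
#' For each lipid, the director `d` is the unit vector from the centroid of
#' its tail beads to its head bead (pointing head-to-water); the reference
#' normal `n` is the global `+z` for the upper leaflet and `-z` for the
#' lower (planar membranes).  The tilt vector is
#' \deqn{t = d / (n \cdot d) - n,} an in-plane 2-vector whose magnitude is
#' `tan(theta)` for a director at angle `theta` from the normal.  Lipids
#' nearly parallel to the membrane plane (`n . d <= 0.1`) are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param frame A [membrane_frame()].
#' @return A `director_field` tibble with columns `molecule_id`, `species`,
#'   `leaflet`, `x`, `y` (head position), `dx`, `dy`, `dz`, `tx`, `ty`, and
#'   attributes `area_per_lipid` (named per leaflet), `n_excluded`, `box`,
#'   `temperature`-free geometry only.
#' @export
compute_directors <- function(frame) {
  box <- frame_box(frame)
  heads <- frame[frame$role == "head", ]
  tails <- frame[frame$role == "tail", ]
  if (nrow(heads) == 0 || nrow(tails) == 0) {
    abort("frame needs head and tail particles.",
          class = "poremech_validation_error")
  }
  hz <- stats::setNames(heads$z, heads$molecule_id)
  hx <- stats::setNames(heads$x, heads$molecule_id)
  hy <- stats::setNames(heads$y, heads$molecule_id)
  key <- as.character(tails$molecule_id)
  # tail displacements relative to the head, minimum image
  rx <- min_image(tails$x - hx[key], box[1])
  ry <- min_image(tails$y - hy[key], box[2])
  rz <- min_image(tails$z - hz[key], box[3])
  cen <- tibble(molecule_id = tails$molecule_id, rx = rx, ry = ry, rz = rz) |>
    group_by(.data$molecule_id) |>
    summarise(rx = mean(.data$rx), ry = mean(.data$ry), rz = mean(.data$rz),
              .groups = "drop")
  # director: tail centroid -> head
  dvec <- cbind(-cen$rx, -cen$ry, -cen$rz)
  norm <- sqrt(rowSums(dvec^2))
  dvec <- dvec / norm
  midplane <- mean(tails$z)
  mol <- cen$molecule_id
  leaflet <- unname(ifelse(hz[as.character(mol)] > midplane, "upper", "lower"))
  nz <- ifelse(leaflet == "upper", 1, -1)
  ndotd <- dvec[, 3] * nz
  keep <- ndotd > 0.1
  n_excluded <- sum(!keep)
  tx <- dvec[, 1] / ndotd
  ty <- dvec[, 2] / ndotd
  sp <- stats::setNames(heads$species, heads$molecule_id)
  out <- tibble(
    molecule_id = mol, species = unname(sp[as.character(mol)]),
    leaflet = leaflet,
    x = unname(hx[as.character(mol)]), y = unname(hy[as.character(mol)]),
    dx = dvec[, 1], dy = dvec[, 2], dz = dvec[, 3],
    tx = tx, ty = ty
  )[keep, ]
  apl <- c(upper = box[1] * box[2] / max(1, sum(leaflet == "upper")),
           lower = box[1] * box[2] / max(1, sum(leaflet == "lower")))
  out <- tibble::new_tibble(out, class = "director_field")
  attr(out, "area_per_lipid") <- apl
  attr(out, "n_excluded") <- n_excluded
  attr(out, "box") <- box
  out
}

#' Tilt modulus from tilt-vector fluctuations
#'
#' Quadratic-fluctuation estimator: for Gaussian tilt statistics each tilt
#' component has variance \eqn{k_B T / (\kappa_\theta A_l)}, so
#' \deqn{\kappa_\theta = k_B T / (\mathrm{var_{pc}}(t) A_l)} with
#' `var_pc` the per-component variance.  A [compute_directors()] field is
#' estimated per leaflet (with their mean reported); a plain two-column
#' table of tilt vectors (e.g. from [sample_tilt_vectors()]) gives a single
#' pooled estimate and requires `area_per_lipid`.
#'
#' @param tilt A `director_field` or a data frame/matrix with two tilt
#'   components per row.
#' @param area_per_lipid Area per lipid (nm^2); taken from the field's
#'   attribute (or the sampling attribute) when absent.
#' @param temperature Temperature (K).
#' @return A tibble with columns `leaflet` (`"upper"`, `"lower"`, `"mean"`,
#'   or `"all"`), `kappa_theta` (kJ mol^-1 nm^-2) and `n`.
#' @export
estimate_tilt_modulus <- function(tilt, area_per_lipid = NULL,
                                  temperature = 310) {
  kT <- thermo_context(temperature)$kT
  one <- function(tx, ty, apl) {
    if (length(tx) < 2) {
      abort("too few tilt vectors.", class = "poremech_validation_error")
    }
    v <- (var(tx) + var(ty)) / 2
    if (v <= 0) {
      abort("zero tilt variance: singular estimate.",
            class = "poremech_singular_error")
    }
    kT / (v * apl)
  }
  if (inherits(tilt, "director_field")) {
    if (nrow(tilt) < 500) {
      abort("need >= 500 lipid tilt vectors.", class = "poremech_validation_error")
    }
    apl <- area_per_lipid %||% attr(tilt, "area_per_lipid")
    per <- tilt |>
      group_by(.data$leaflet) |>
      summarise(kappa_theta = one(.data$tx, .data$ty,
                                  if (length(apl) > 1) apl[[unique(.data$leaflet)]]
                                  else apl),
                n = n(), .groups = "drop")
    bind_rows(per, tibble(leaflet = "mean",
                          kappa_theta = mean(per$kappa_theta),
                          n = sum(per$n)))
  } else {
    m <- as.data.frame(tilt)
    apl <- area_per_lipid %||% attr(tilt, "area_per_lipid")
    if (is.null(apl)) {
      abort("`area_per_lipid` is required for plain tilt samples.",
            class = "poremech_validation_error")
    }
    if (nrow(m) < 500) {
      abort("need >= 500 tilt vectors.", class = "poremech_validation_error")
    }
    tibble(leaflet = "all", kappa_theta = one(m[[1]], m[[2]], apl), n = nrow(m))
  }
}

#' Splay values from a director field
#'
#' Pairwise splay between neighbouring lipids of the same leaflet:
#' \eqn{S = (d_2 - d_1)\cdot \hat r_{12} / |r_{12}|} for in-plane
#' (minimum-image) separations within `pair_range` (default 0.5-1.0 nm).
#'
#' @param field A [compute_directors()] field.
#' @param pair_range Allowed in-plane separation (nm).
#' @return Numeric vector of splay samples (nm^-1) with an
#'   `area_per_lipid` attribute (leaflet mean).
#' @export
splay_from_directors <- function(field, pair_range = c(0.5, 1.0)) {
  box <- attr(field, "box")
  vals <- unlist(lapply(split(seq_len(nrow(field)), field$leaflet), function(ii) {
    f <- field[ii, ]
    n <- nrow(f)
    if (n < 2) return(numeric(0))
    pr <- utils::combn(n, 2)
    dx <- min_image(f$x[pr[2, ]] - f$x[pr[1, ]], box[1])
    dy <- min_image(f$y[pr[2, ]] - f$y[pr[1, ]], box[2])
    r <- sqrt(dx^2 + dy^2)
    sel <- r >= pair_range[1] & r <= pair_range[2]
    ddx <- f$dx[pr[2, sel]] - f$dx[pr[1, sel]]
    ddy <- f$dy[pr[2, sel]] - f$dy[pr[1, sel]]
    (ddx * dx[sel] + ddy * dy[sel]) / r[sel]^2
  }), use.names = FALSE)
  attr(vals, "area_per_lipid") <- mean(attr(field, "area_per_lipid"))
  vals
}

#' Bending modulus from splay fluctuations
#'
#' Quadratic-fluctuation estimator for the monolayer bending modulus: for
#' Gaussian splay statistics \eqn{\kappa = k_B T / (\mathrm{var}(S) A_l)}.
#' Accepts a numeric vector of splay samples (from
#' [sample_splay_values()] or [splay_from_directors()]) or a
#' `director_field`, in which case pair splays are computed first.
#'
#' @param splay Numeric splay samples (nm^-1) or a `director_field`.
#' @param area_per_lipid Area per lipid (nm^2); attribute fallback as in
#'   [estimate_tilt_modulus()].
#' @param temperature Temperature (K).
#' @param min_samples Minimum number of samples required.
#' @return A one-row tibble: `kappa` (kJ/mol), `splay_mean` (nm^-1, an
#'   estimate of the spontaneous curvature for symmetric sampling), `n`.
#' @export
estimate_bending_modulus <- function(splay, area_per_lipid = NULL,
                                     temperature = 310, min_samples = 1e4) {
  if (inherits(splay, "director_field")) {
    splay <- splay_from_directors(splay)
    min_samples <- min(min_samples, 100)
  }
  apl <- area_per_lipid %||% attr(splay, "area_per_lipid")
  if (is.null(apl)) {
    abort("`area_per_lipid` is required.", class = "poremech_validation_error")
  }
  s <- as.numeric(splay)
  if (length(s) < min_samples) {
    abort(sprintf("need >= %g splay samples.", min_samples),
          class = "poremech_validation_error")
  }
  v <- var(s)
  if (v <= 0) {
    abort("zero splay variance: singular estimate.",
          class = "poremech_singular_error")
  }
  kT <- thermo_context(temperature)$kT
  tibble(kappa = kT / (v * apl), splay_mean = mean(s), n = length(s))
}

#' Spontaneous curvature from a lateral stress profile
#'
#' First-moment method: the monolayer torque about the pivot (neutral)
#' plane equals \eqn{\kappa J_s}, so
#' \deqn{J_s = \kappa^{-1} \int_{leaflet} (z - z_{pivot})\, s(z)\, dz}
#' by trapezoidal quadrature over the leaflet bounds.  The sign convention
#' is positive for a monolayer curving towards its head groups; for the
#' lower leaflet the integral sign is flipped so both leaflets of a
#' symmetric profile report the same `J_s`.
#'
#' @param profile A `stress_profile` (see [make_stress_profile()]), or any
#'   tibble with `z`, `s` columns plus `leaflet_bounds`/`pivot` attributes.
#' @param kappa Monolayer bending modulus (kJ/mol, > 0).
#' @param pivot Pivot-plane position (nm); defaults to the profile's
#'   `pivot` attribute, else the leaflet midpoint.  Must lie inside the
#'   leaflet.
#' @param leaflet `"upper"` or `"lower"`.
#' @return Spontaneous curvature (nm^-1).
#' @export
spontaneous_curvature <- function(profile, kappa, pivot = NULL,
                                  leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  stopifnot_scalar_number(kappa, "kappa", min = 1e-12)
  bounds <- attr(profile, "leaflet_bounds")[[leaflet]]
  if (is.null(bounds)) {
    abort("profile has no leaflet bounds.", class = "poremech_validation_error")
  }
  pivot <- pivot %||% {
    p <- attr(profile, "pivot")
    if (is.null(p)) mean(bounds) else if (leaflet == "lower") -p else p
  }
  if (pivot < bounds[1] || pivot > bounds[2]) {
    abort("`pivot` lies outside the leaflet bounds.",
          class = "poremech_validation_error")
  }
  sel <- profile$z >= bounds[1] - 1e-12 & profile$z <= bounds[2] + 1e-12
  z <- profile$z[sel]
  f <- (z - pivot) * profile$s[sel]
  moment <- sum(diff(z) * (head(f, -1) + tail(f, -1)) / 2)
  if (leaflet == "lower") moment <- -moment
  moment / kappa
}

#' Hydrophobic core thickness from density crossings
#'
#' Histograms the tail-bead and water-bead densities along z (0.1 nm bins,
#' each normalized to its plateau), and returns the distance between the
#' two z positions where the profiles cross (linear interpolation between
#' bin centres): the thickness of the water-free acyl-chain core.
#'
#' @param frame A [membrane_frame()].
#' @param bin Histogram bin width (nm).
#' @return Thickness in nm.
#' @export
hydrophobic_thickness <- function(frame, bin = 0.1) {
  tz <- frame$z[frame$role == "tail"]
  wz <- frame$z[is_polar_role(frame$role)]
  if (length(tz) == 0 || length(wz) == 0) {
    abort("frame needs both tail and water particles.",
          class = "poremech_degenerate_error")
  }
  box_z <- frame_box(frame)[3]
  breaks <- seq(0, box_z + bin, by = bin)
  ht <- graphics::hist(tz, breaks = breaks, plot = FALSE)$counts
  hw <- graphics::hist(wz, breaks = breaks, plot = FALSE)$counts
  f <- ht / max(ht) - hw / max(hw)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  sgn <- sign(f)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross) < 2) {
    abort("no two density crossings found: degenerate frame.",
          class = "poremech_degenerate_error")
  }
  interp <- vapply(cross, function(i) {
    mids[i] + (0 - f[i]) * (mids[i + 1] - mids[i]) / (f[i + 1] - f[i])
  }, numeric(1))
  max(interp) - min(interp)
}
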