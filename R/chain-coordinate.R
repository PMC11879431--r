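#' Cylinder specification for the pore coordinate
#'
#' Defines the analysis cylinder on which the joint pore
#' nucleation/expansion coordinate is evaluated: its lateral centre
#' (`"auto"` = densest polar column, tracking a drifting defect), radius,
#' vertical extent over the hydrophobic core, slice discretization,
#' per-slice saturation count and the nucleated-pore radius `R0` that sets
#' the coordinate's length unit on the expansion branch.
#'
#' `z_min`/`z_max` default to the frame's tail-density region (resolved per
#' frame), coupling the coordinate to the hydrophobic-thickness analysis.
#'
#' @param center_xy `"auto"` or `c(x, y)` in nm.
#' @param radius Cylinder radius (nm).
#' @param z_min,z_max Core bounds (nm, absolute frame coordinates); `NULL`
#'   resolves them from the tail density.
#' @param slice_thickness Target slice thickness (nm); the slice count is
#'   derived from it when `n_slices` is `NULL`.
#' @param n_slices Number of z slices (>= 10) overriding `slice_thickness`.
#' @param n_sat Polar-particle count at which a slice saturates.
#' @param R0 Nucleated-pore radius (nm).
#' @return A `cylinder_spec` list.
#' @export
cylinder_spec <- function(center_xy = "auto", radius = 1.2, z_min = NULL,
                          z_max = NULL, slice_thickness = 0.1,
                          n_slices = NULL, n_sat = 1, R0 = 0.4) {
  stopifnot_scalar_number(radius, "radius", min = 1e-9)
  stopifnot_scalar_number(n_sat, "n_sat", min = 1)
  stopifnot_scalar_number(R0, "R0", min = 1e-9)
  if (!is.null(n_slices)) stopifnot_scalar_number(n_slices, "n_slices", min = 10)
  structure(
    list(center_xy = center_xy, radius = radius, z_min = z_min, z_max = z_max,
         slice_thickness = slice_thickness, n_slices = n_slices,
         n_sat = n_sat, R0 = R0),
    class = "cylinder_spec"
  )
}

# Core z bounds from the tail-density region (bins where the tail histogram
# reaches at least half its maximum).
core_z_bounds <- function(frame, bin = 0.1) {
  tz <- frame$z[frame$role == "tail"]
  if (length(tz) == 0) {
    abort("frame has no tail particles; cannot locate the hydrophobic core.",
          class = "poremech_validation_error")
  }
  box_z <- frame_box(frame)[3]
  breaks <- seq(0, box_z + bin, by = bin)
  h <- graphics::hist(tz, breaks = breaks, plot = FALSE)
  dense <- which(h$counts >= max(h$counts) / 2)
  c(h$breaks[min(dense)], h$breaks[max(dense) + 1])
}

# Resolve "auto"/NULL fields of a cylinder spec against a concrete frame.
resolve_cylinder <- function(frame, cyl) {
  box <- frame_box(frame)
  zb <- c(cyl$z_min %||% NA_real_, cyl$z_max %||% NA_real_)
  if (any(is.na(zb))) {
    core <- core_z_bounds(frame)
    if (is.na(zb[1])) zb[1] <- core[1]
    if (is.na(zb[2])) zb[2] <- core[2]
  }
  if (zb[2] <= zb[1]) {
    abort("`z_max` must exceed `z_min`.", class = "poremech_validation_error")
  }
  n_slices <- cyl$n_slices %||% max(10L, as.integer(round((zb[2] - zb[1]) /
                                                            cyl$slice_thickness)))
  center <- cyl$center_xy
  if (identical(center, "auto")) {
    center <- auto_pore_center(frame, radius = cyl$radius, z_bounds = zb)
  }
  list(center = center, radius = cyl$radius, z_min = zb[1], z_max = zb[2],
       n_slices = n_slices, n_sat = cyl$n_sat, R0 = cyl$R0)
}

#' Locate the pore axis as the densest polar column
#'
#' Scans a 0.2 nm lateral grid and returns the grid point whose cylinder
#' (minimum-image) contains the most polar particles within the core z
#' bounds; ties break towards the first grid point (deterministic).  Falls
#' back to the box centre when the core is dry.
#'
#' @param frame A [membrane_frame()].
#' @param radius Cylinder radius (nm).
#' @param z_bounds Core bounds; `NULL` resolves from the tail density.
#' @param grid_spacing Lateral grid spacing (nm).
#' @return `c(x, y)` in nm.
#' @export
auto_pore_center <- function(frame, radius = 1.2, z_bounds = NULL,
                             grid_spacing = 0.2) {
  box <- frame_box(frame)
  zb <- z_bounds %||% core_z_bounds(frame)
  pol <- frame[is_polar_role(frame$role) & frame$z >= zb[1] & frame$z < zb[2], ]
  if (nrow(pol) == 0) return(c(box[1] / 2, box[2] / 2))
  gx <- seq(grid_spacing / 2, box[1], by = grid_spacing)
  gy <- seq(grid_spacing / 2, box[2], by = grid_spacing)
  cand <- expand.grid(x = gx, y = gy)
  dx <- min_image(outer(pol$x, cand$x, "-"), box[1])
  dy <- min_image(outer(pol$y, cand$y, "-"), box[2])
  counts <- colSums(dx * dx + dy * dy <= radius^2)
  best <- which.max(counts)
  c(cand$x[best], cand$y[best])
}

#' Per-slice polar occupancy of the analysis cylinder
#'
#' Slices the hydrophobic core into `n_slices` z slabs and counts the polar
#' particles (roles `water`/`polar`) whose lateral minimum-image distance
#' to the cylinder axis is at most the cylinder radius.  The continuous
#' slice indicator is a linear ramp `delta = min(1, count / n_sat)`.
#'
#' @param frame A [membrane_frame()].
#' @param cyl A [cylinder_spec()].
#' @return A `slice_occupancy` tibble with columns `slice`, `z_lo`, `z_hi`,
#'   `z_mid`, `count`, `delta`, and attributes `center`, `radius`,
#'   `z_bounds`, `n_polar`, `height`, `R0`, `n_sat`.
#' @export
slice_occupancy <- function(frame, cyl = cylinder_spec()) {
  if (nrow(frame) == 0) {
    abort("empty frame.", class = "poremech_validation_error")
  }
  rc <- resolve_cylinder(frame, cyl)
  box <- frame_box(frame)
  pol <- frame[is_polar_role(frame$role), ]
  dx <- min_image(pol$x - rc$center[1], box[1])
  dy <- min_image(pol$y - rc$center[2], box[2])
  inside <- (dx * dx + dy * dy <= rc$radius^2) &
    pol$z >= rc$z_min & pol$z < rc$z_max
  breaks <- seq(rc$z_min, rc$z_max, length.out = rc$n_slices + 1)
  idx <- findInterval(pol$z[inside], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = rc$n_slices)
  out <- tibble(
    slice = seq_len(rc$n_slices),
    z_lo = breaks[-length(breaks)], z_hi = breaks[-1],
    z_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts,
    delta = pmin(1, counts / rc$n_sat)
  )
  out <- tibble::new_tibble(out, class = "slice_occupancy")
  attr(out, "center") <- rc$center
  attr(out, "radius") <- rc$radius
  attr(out, "z_bounds") <- c(rc$z_min, rc$z_max)
  attr(out, "n_polar") <- sum(inside)
  attr(out, "height") <- rc$z_max - rc$z_min
  attr(out, "R0") <- rc$R0
  attr(out, "n_sat") <- rc$n_sat
  out
}

#' Connectivity branch of the pore coordinate
#'
#' The mean slice indicator, \eqn{\xi_{chain} = N_s^{-1} \sum_s \delta_s
#' \in [0, 1]}: the fractional connectivity of a polar transmembrane
#' defect.  1 means every core slice holds a polar particle (a continuous
#' water wire).
#'
#' @param occ A [slice_occupancy()] table.
#' @return Value in `[0, 1]`.
#' @export
xi_chain <- function(occ) mean(occ$delta)

#' Effective pore radius from polar-particle volume
#'
#' For a spanning defect, the open pore is modelled as a water-filled
#' cylinder: \eqn{\hat R = \sqrt{N_p \bar v / (\pi h)}} with `N_p` the
#' polar particles inside the analysis cylinder over the core of height
#' `h` and `v_particle` the per-particle volume (default 0.030 nm^3, one
#' water).
#'
#' @param frame A [membrane_frame()].
#' @param cyl A [cylinder_spec()].
#' @param v_particle Per-particle volume (nm^3).
#' @return Estimated pore radius (nm).
#' @export
pore_radius_estimate <- function(frame, cyl = cylinder_spec(),
                                 v_particle = 0.030) {
  occ <- slice_occupancy(frame, cyl)
  if (xi_chain(occ) < 0.99) {
    abort("no spanning polar defect: pore radius is undefined below xi_chain = 0.99.",
          class = "poremech_state_error")
  }
  sqrt(attr(occ, "n_polar") * v_particle / (pi * attr(occ, "height")))
}

#' Joint pore nucleation/expansion coordinate
#'
#' Evaluates the pore coordinate on a frame: below the connectivity
#' threshold (`xi_chain < 1 - eps`) the coordinate is the defect
#' connectivity itself; once a spanning defect exists it switches to the
#' pore radius in units of `R0`, clamped at 1 so the two branches join
#' continuously (a bare water wire has `R_hat < R0`).
#'
#' @inheritParams pore_radius_estimate
#' @param eps Branch-switch threshold.
#' @return A single numeric value (>= 0).
#' @seealso [xi_report()] for the full per-frame breakdown.
#' @export
xi_pore <- function(frame, cyl = cylinder_spec(), eps = 0.01,
                    v_particle = 0.030) {
  occ <- slice_occupancy(frame, cyl)
  xc <- xi_chain(occ)
  if (xc < 1 - eps) return(xc)
  r_hat <- sqrt(attr(occ, "n_polar") * v_particle /
                  (pi * attr(occ, "height")))
  max(1, r_hat / attr(occ, "R0"))
}

#' Full pore-coordinate report for a frame
#'
#' @inheritParams xi_pore
#' @return A one-row tibble: `xi_chain`, `R_hat` (NA below the spanning
#'   threshold), `xi_p`, `n_polar`, `center_x`, `center_y`.
#' @export
xi_report <- function(frame, cyl = cylinder_spec(), eps = 0.01,
                      v_particle = 0.030) {
  occ <- slice_occupancy(frame, cyl)
  xc <- xi_chain(occ)
  r_hat <- sqrt(attr(occ, "n_polar") * v_particle /
                  (pi * attr(occ, "height")))
  xp <- if (xc < 1 - eps) xc else max(1, r_hat / attr(occ, "R0"))
  ctr <- attr(occ, "center")
  tibble(
    xi_chain = xc,
    R_hat = if (xc >= 0.99) r_hat else NA_real_,
    xi_p = xp,
    n_polar = attr(occ, "n_polar"),
    center_x = ctr[1], center_y = ctr[2]
  )
}
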