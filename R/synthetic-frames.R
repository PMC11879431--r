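#' Largest-remainder apportionment of species counts
#'
#' Deterministically converts species fractions into integer counts that sum
#' exactly to `n`: each species gets `floor(n * f)`, and the remaining slots
#' go to the largest fractional remainders (ties broken by input order).
#'
#' @param fractions Named numeric vector of species fractions; must sum to 1
#'   within 1e-9.
#' @param n Total count to apportion.
#' @return Named integer vector summing to `n`.
#' @examples
#' species_counts(c(POPC = 0.7, CHOL = 0.3), 200)
#' @export
species_counts <- function(fractions, n) {
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    abort("`fractions` must be a named vector.", class = "poremech_validation_error")
  }
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    abort("species fractions must be non-negative and sum to 1 (within 1e-9).",
          class = "poremech_validation_error")
  }
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

# Water bead number density [nm^-3]; the inverse of the default per-particle
# volume (0.030 nm^3, one water) used by pore_radius_estimate().
.water_number_density <- 1 / 0.030

# gap between the hydrophobic core edge and the first water layer [nm]
.water_gap <- 0.02

# Internal flat-bilayer builder; assumes the RNG state is already seeded.
# Coordinates put the bilayer midplane at box_z/2.
build_flat <- function(n_lipids_per_leaflet, species_fractions, box_xy, d_hc,
                       water_pad = 0.8, jitter = 0.15) {
  stopifnot_scalar_number(n_lipids_per_leaflet, "n_lipids_per_leaflet", min = 4)
  stopifnot_scalar_number(box_xy, "box_xy", min = 1e-6)
  stopifnot_scalar_number(d_hc, "d_hc", min = 1e-6)
  counts <- species_counts(species_fractions, n_lipids_per_leaflet)

  k <- ceiling(sqrt(n_lipids_per_leaflet))
  spacing <- box_xy / k
  if (spacing < 0.4) {
    abort("box too small for the lipid count at >= 0.4 nm lattice spacing.",
          class = "poremech_geometry_error")
  }
  box_z <- d_hc + 2 * (.water_gap + water_pad) + 0.4
  mid <- box_z / 2
  half <- d_hc / 2

  one_leaflet <- function(sign, mol_offset) {
    idx <- seq_len(n_lipids_per_leaflet) - 1L
    lat_x <- (idx %% k + 0.5) * spacing
    lat_y <- (idx %/% k + 0.5) * spacing
    jx <- runif(n_lipids_per_leaflet, -jitter, jitter)
    jy <- runif(n_lipids_per_leaflet, -jitter, jitter)
    species <- sample(rep(names(counts), counts))
    mol <- mol_offset + seq_len(n_lipids_per_leaflet)
    head <- tibble(
      x = lat_x + jx, y = lat_y + jy, z = mid + sign * half,
      species = species, role = "head", molecule_id = mol
    )
    # two tail beads per lipid, filling the leaflet half of the core
    t1z <- mid + sign * runif(n_lipids_per_leaflet, 0, half / 2)
    t2z <- mid + sign * runif(n_lipids_per_leaflet, half / 2, half)
    tails <- tibble(
      x = rep(lat_x + jx, 2) + runif(2 * n_lipids_per_leaflet, -0.05, 0.05),
      y = rep(lat_y + jy, 2) + runif(2 * n_lipids_per_leaflet, -0.05, 0.05),
      z = c(t1z, t2z),
      species = rep(species, 2), role = "tail", molecule_id = rep(mol, 2)
    )
    bind_rows(head, tails)
  }

  upper <- one_leaflet(+1, 0L)
  lower <- one_leaflet(-1, n_lipids_per_leaflet)

  water_slab <- function(z_lo, z_hi, mol_offset) {
    nw <- round(box_xy^2 * (z_hi - z_lo) * .water_number_density)
    tibble(
      x = runif(nw, 0, box_xy), y = runif(nw, 0, box_xy),
      z = runif(nw, z_lo, z_hi),
      species = "W", role = "water",
      molecule_id = mol_offset + seq_len(nw)
    )
  }
  w_top <- water_slab(mid + half + .water_gap, mid + half + .water_gap + water_pad,
                      2L * n_lipids_per_leaflet)
  w_bot <- water_slab(mid - half - .water_gap - water_pad, mid - half - .water_gap,
                      2L * n_lipids_per_leaflet + nrow(w_top))

  frame <- membrane_frame(bind_rows(upper, lower, w_top, w_bot),
                          box = c(box_xy, box_xy, box_z))
  attr(frame, "d_hc") <- d_hc
  frame
}

#' Generate a flat toy bilayer
#'
#' Builds a coarse placeholder membrane: one head bead per lipid at
#' `z = +/- d_hc/2`, two tail beads filling the hydrophobic core, and water
#' slabs above and below the membrane at bulk bead density (1 bead per
#' 0.030 nm^3).  Lipids sit on a jittered square lattice; species are
#' apportioned by largest-remainder rounding and shuffled over lattice sites.
#' The hydrophobic core is dry by construction.
#'
#' These frames are geometric fixtures for the reaction-coordinate, moduli
#' and sorting stages; they carry no molecular mechanics.
#'
#' @param n_lipids_per_leaflet Number of lipids per leaflet (>= 4).
#' @param species_fractions Named fractions per lipid species, summing to 1.
#' @param box_xy Lateral box edge (nm).
#' @param d_hc Hydrophobic core thickness (nm); heads sit at `+/- d_hc/2`
#'   from the midplane.
#' @param seed Integer seed; fixed seed gives bit-identical frames.
#' @param water_pad Thickness of each water slab (nm).
#' @param jitter Maximum lateral lattice jitter (nm).
#' @return A [membrane_frame()] with the bilayer midplane at half the box
#'   height and a `d_hc` attribute.
#' @examples
#' fr <- make_flat_membrane(36, c(POPC = 1), box_xy = 5, d_hc = 2.8, seed = 1)
#' count_lipids(fr)
#' @export
make_flat_membrane <- function(n_lipids_per_leaflet, species_fractions,
                               box_xy, d_hc = 2.8, seed = NULL,
                               water_pad = 0.8, jitter = 0.15) {
  with_seed(seed, build_flat(n_lipids_per_leaflet, species_fractions, box_xy,
                             d_hc, water_pad = water_pad, jitter = jitter))
}

#' Generate a toy membrane with an open toroidal pore
#'
#' Starts from a flat bilayer, removes the lipids over the pore footprint,
#' places rim lipids with their head beads on a half-torus of tube radius
#' `d_hc/2` around the pore, and fills the central cylinder of radius
#' `pore_radius` with water beads at bulk density.  Rim species are drawn
#' with probability proportional to bulk fraction times the per-species
#' enrichment factor (renormalized); a factor of 0 excludes a species from
#' the rim entirely.
#'
#' The number of rim lipids is set so that the rim area per lipid matches
#' the bulk area per lipid, keeping rim and bulk densities comparable.
#'
#' @inheritParams make_flat_membrane
#' @param pore_radius Pore (waist) radius in nm, >= 0.3.
#' @param rim_enrichment Named numeric factors (>= 0) per species; species
#'   not named get factor 1.
#' @return A [membrane_frame()] with attributes `d_hc`, `pore_radius` and
#'   `pore_center` (x, y).
#' @examples
#' fr <- make_pore_membrane(64, c(POPC = 0.8, LPC = 0.2), box_xy = 8,
#'                          d_hc = 2.8, pore_radius = 0.8,
#'                          rim_enrichment = c(LPC = 2), seed = 1)
#' @export
make_pore_membrane <- function(n_lipids_per_leaflet, species_fractions,
                               box_xy, d_hc = 2.8, pore_radius,
                               rim_enrichment = NULL, seed = NULL,
                               water_pad = 0.8, jitter = 0.15) {
  stopifnot_scalar_number(pore_radius, "pore_radius", min = 0.3)
  a <- d_hc / 2
  if (pore_radius + a > box_xy / 2) {
    abort("pore_radius + d_hc/2 exceeds half the lateral box edge.",
          class = "poremech_geometry_error")
  }
  if (!is.null(rim_enrichment) && any(rim_enrichment < 0)) {
    abort("rim enrichment factors must be >= 0.",
          class = "poremech_validation_error")
  }

  with_seed(seed, {
    flat <- build_flat(n_lipids_per_leaflet, species_fractions, box_xy, d_hc,
                       water_pad = water_pad, jitter = jitter)
    box <- frame_box(flat)
    mid <- box[3] / 2
    cx <- box_xy / 2
    cy <- box_xy / 2
    r_c <- pore_radius + a

    # drop lipid molecules whose head lies over the pore footprint
    heads <- flat[flat$role == "head", ]
    dx <- min_image(heads$x - cx, box[1])
    dy <- min_image(heads$y - cy, box[2])
    drop_mol <- heads$molecule_id[sqrt(dx^2 + dy^2) < r_c]
    keep <- !(flat$molecule_id %in% drop_mol & flat$role %in% c("head", "tail"))
    body <- flat[keep, ]

    # rim lipids on the half-torus, matching the bulk area per lipid
    area_l <- box_xy^2 / n_lipids_per_leaflet
    rim_area <- 2 * pi * a * (pi * r_c - 2 * a)
    n_rim <- max(4L, as.integer(round(rim_area / area_l)))

    # sample theta in [-pi/2, pi/2] with area weight rho(theta) = r_c - a*cos(theta)
    theta <- numeric(0)
    while (length(theta) < n_rim) {
      cand <- runif(2 * n_rim, -pi / 2, pi / 2)
      accept <- runif(2 * n_rim) < (r_c - a * cos(cand)) / r_c
      theta <- c(theta, cand[accept])
    }
    theta <- theta[seq_len(n_rim)]
    phi <- runif(n_rim, 0, 2 * pi)
    rho <- r_c - a * cos(theta)

    fr <- species_fractions[names(species_fractions)]
    w <- fr
    if (!is.null(rim_enrichment)) {
      e <- rim_enrichment[names(fr)]
      e[is.na(e)] <- 1
      w <- fr * e
    }
    if (sum(w) <= 0) {
      abort("rim species weights are all zero.", class = "poremech_validation_error")
    }
    w <- w / sum(w)
    rim_species <- sample(names(w), n_rim, replace = TRUE, prob = w)

    hx <- cx + rho * cos(phi)
    hy <- cy + rho * sin(phi)
    hz <- mid + a * sin(theta)
    # tails point from the head towards the torus tube centre
    tcx <- cx + r_c * cos(phi)
    tcy <- cy + r_c * sin(phi)
    ux <- (tcx - hx) / a
    uy <- (tcy - hy) / a
    uz <- (mid - hz) / a
    mol0 <- max(flat$molecule_id)
    mol <- mol0 + seq_len(n_rim)
    rim <- bind_rows(
      tibble(x = hx, y = hy, z = hz, species = rim_species, role = "head",
             molecule_id = mol),
      tibble(x = hx + ux * a / 3, y = hy + uy * a / 3, z = hz + uz * a / 3,
             species = rim_species, role = "tail", molecule_id = mol),
      tibble(x = hx + ux * 2 * a / 3, y = hy + uy * 2 * a / 3,
             z = hz + uz * 2 * a / 3,
             species = rim_species, role = "tail", molecule_id = mol)
    )

    # fill the pore cylinder with water at bulk bead density
    nw <- round(pi * pore_radius^2 * d_hc * .water_number_density)
    rw <- pore_radius * sqrt(runif(nw))
    aw <- runif(nw, 0, 2 * pi)
    pore_w <- tibble(
      x = cx + rw * cos(aw), y = cy + rw * sin(aw),
      z = runif(nw, mid - a, mid + a),
      species = "W", role = "water",
      molecule_id = mol0 + n_rim + seq_len(nw)
    )

    out <- membrane_frame(bind_rows(body, rim, pore_w), box = box)
    attr(out, "d_hc") <- d_hc
    attr(out, "pore_radius") <- pore_radius
    attr(out, "pore_center") <- c(cx, cy)
    out
  })
}

#' Generate a toy membrane with a transmembrane water wire
#'
#' Adds a single-file column of water beads spanning the hydrophobic core of
#' a flat bilayer, one bead per 0.1 nm of core height, so that every 0.1 nm
#' slice of the core holds at least one polar particle (the fully connected
#' defect state of the pore coordinate).
#'
#' @inheritParams make_flat_membrane
#' @param wire_radius Lateral extent of the column (nm), in `[0.1, 0.4]`.
#' @param center_xy Optional `c(x, y)` position of the wire; defaults to the
#'   box centre.
#' @return A [membrane_frame()] with attributes `d_hc` and `wire_center`.
#' @export
make_water_wire <- function(n_lipids_per_leaflet, species_fractions, box_xy,
                            d_hc = 2.8, wire_radius = 0.15, center_xy = NULL,
                            seed = NULL, water_pad = 0.8, jitter = 0.15) {
  if (wire_radius < 0.1 || wire_radius > 0.4) {
    abort("`wire_radius` must lie in [0.1, 0.4] nm.",
          class = "poremech_validation_error")
  }
  with_seed(seed, {
    flat <- build_flat(n_lipids_per_leaflet, species_fractions, box_xy, d_hc,
                       water_pad = water_pad, jitter = jitter)
    box <- frame_box(flat)
    mid <- box[3] / 2
    ctr <- center_xy %||% c(box_xy / 2, box_xy / 2)
    half <- d_hc / 2
    zs <- mid + seq(-half + 0.05, half - 0.05, by = 0.1)
    nw <- length(zs)
    rr <- wire_radius * sqrt(runif(nw))
    aa <- runif(nw, 0, 2 * pi)
    wire <- tibble(
      x = ctr[1] + rr * cos(aa), y = ctr[2] + rr * sin(aa), z = zs,
      species = "W", role = "water",
      molecule_id = max(flat$molecule_id) + seq_len(nw)
    )
    out <- membrane_frame(bind_rows(flat, wire), box = box)
    attr(out, "d_hc") <- d_hc
    attr(out, "wire_center") <- ctr
    out
  })
}
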