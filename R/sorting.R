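#' Cylindrical species density map around the pore axis
#'
#' Bins particle mass per species into (r, z) cells around the pore axis:
#' `r` is the lateral minimum-image distance to the axis, `z` the normal
#' distance from the membrane midplane (the mean tail-bead height of each
#' frame).  Densities are the binned mass divided by the cylindrical-shell
#' bin volume \eqn{\pi (r_{i+1}^2 - r_i^2)\Delta z} and the number of
#' frames.
#'
#' @param frames A [membrane_frame()] or a list of frames.
#' @param species Character vector of species to map; default all species
#'   present in the first frame.
#' @param axis `"auto"` (the [auto_pore_center()] of each frame, tracking
#'   a drifting pore) or a fixed `c(x, y)`.
#' @param dr,dz Bin widths (nm).
#' @param r_max Outer radius (nm); capped at half the smaller lateral box
#'   edge (with a warning when the request exceeds it).
#' @param z_max Half-height of the map (nm); defaults to half the box
#'   height.
#' @param masses Named per-particle masses by species (default 1 for all:
#'   bead-count density).
#' @return A `density_map` tibble with columns `species`, `r_lo`, `r_hi`,
#'   `r_mid`, `z_lo`, `z_hi`, `z_mid`, `density`, and attributes
#'   `r_edges`, `z_edges`, `n_frames`, `masses`.
#' @export
density_map <- function(frames, species = NULL, axis = "auto", dr = 0.2,
                        dz = 0.2, r_max = NULL, z_max = NULL, masses = NULL) {
  if (is_membrane_frame(frames)) frames <- list(frames)
  if (length(frames) < 1) {
    abort("need at least one frame.", class = "poremech_validation_error")
  }
  box <- frame_box(frames[[1]])
  species <- species %||% sort(unique(frames[[1]]$species))
  half_xy <- min(box[1], box[2]) / 2
  if (!is.null(r_max) && r_max > half_xy) {
    warn("`r_max` exceeds half the box edge; truncating.")
    r_max <- half_xy
  }
  r_max <- r_max %||% half_xy
  z_max <- z_max %||% (box[3] / 2)
  r_edges <- seq(0, r_max, by = dr)
  if (max(r_edges) < r_max - 1e-9) r_edges <- c(r_edges, r_max)
  z_edges <- seq(-z_max, z_max, by = dz)
  if (max(z_edges) < z_max - 1e-9) z_edges <- c(z_edges, z_max)
  nr <- length(r_edges) - 1
  nz <- length(z_edges) - 1

  acc <- array(0, dim = c(nr, nz, length(species)),
               dimnames = list(NULL, NULL, species))
  acc_vec <- as.vector(acc)
  for (fr in frames) {
    b <- frame_box(fr)
    ctr <- if (identical(axis, "auto")) auto_pore_center(fr) else axis
    mid <- mean(fr$z[fr$role == "tail"])
    sel <- fr$species %in% species
    p <- fr[sel, ]
    dx <- min_image(p$x - ctr[1], b[1])
    dy <- min_image(p$y - ctr[2], b[2])
    r <- sqrt(dx^2 + dy^2)
    zc <- p$z - mid
    ok <- r < max(r_edges) & zc >= min(z_edges) & zc < max(z_edges)
    ri <- findInterval(r[ok], r_edges, rightmost.closed = TRUE, all.inside = TRUE)
    zi <- findInterval(zc[ok], z_edges, rightmost.closed = TRUE, all.inside = TRUE)
    si <- match(p$species[ok], species)
    m <- if (is.null(masses)) rep(1, sum(ok)) else {
      mm <- masses[p$species[ok]]
      mm[is.na(mm)] <- 1
      mm
    }
    lin <- (si - 1L) * nr * nz + (zi - 1L) * nr + ri
    sums <- rowsum(m, lin)
    at <- as.integer(rownames(sums))
    acc_vec[at] <- acc_vec[at] + sums[, 1]
  }
  acc <- array(acc_vec, dim = dim(acc), dimnames = dimnames(acc))

  vol <- outer(pi * (r_edges[-1]^2 - r_edges[-(nr + 1)]^2), diff(z_edges))
  grid <- tidyr::expand_grid(
    species = species,
    zi = seq_len(nz),
    ri = seq_len(nr)
  )
  dens <- acc[cbind(grid$ri, grid$zi, match(grid$species, species))] /
    (vol[cbind(grid$ri, grid$zi)] * length(frames))
  out <- tibble(
    species = grid$species,
    r_lo = r_edges[grid$ri], r_hi = r_edges[grid$ri + 1],
    z_lo = z_edges[grid$zi], z_hi = z_edges[grid$zi + 1],
    density = dens
  ) |>
    mutate(r_mid = (.data$r_lo + .data$r_hi) / 2,
           z_mid = (.data$z_lo + .data$z_hi) / 2, .after = "z_hi")
  out <- tibble::new_tibble(out, class = "density_map")
  attr(out, "r_edges") <- r_edges
  attr(out, "z_edges") <- z_edges
  attr(out, "n_frames") <- length(frames)
  attr(out, "masses") <- masses
  out
}

#' Density relative to the bulk membrane
#'
#' Divides each (r, z) bin by the volume-weighted mean bulk density of the
#' same species at the same z (bulk = bins with `r_mid >= r_bulk`).  When a
#' z row has no bulk mass for a species, the species' overall bulk mean is
#' used as fallback; bins whose reference is zero are masked (`NA`).
#' Head and tail beads concentrate at different heights, so the per-z
#' normalization keeps the ratio meaningful across the membrane profile.
#'
#' @param map A [density_map()].
#' @param r_bulk Inner edge of the bulk region (nm); default 0.75 of the
#'   outer map radius.  Needs >= 2 bulk bins.
#' @return A `relative_density_map` tibble like the input with a `ratio`
#'   column; attribute `r_bulk`.
#' @export
relative_density <- function(map, r_bulk = NULL) {
  r_edges <- attr(map, "r_edges")
  r_bulk <- r_bulk %||% (0.75 * max(r_edges))
  bulk_bins <- unique(map$r_mid[map$r_mid >= r_bulk])
  if (length(bulk_bins) < 2 || r_bulk > max(r_edges)) {
    abort("bulk region needs >= 2 radial bins inside the map.",
          class = "poremech_validation_error")
  }
  vol_of <- function(d) pi * (d$r_hi^2 - d$r_lo^2) * (d$z_hi - d$z_lo)
  overall <- map |>
    filter(.data$r_mid >= r_bulk) |>
    group_by(.data$species) |>
    summarise(ref_all = sum(.data$density * vol_of(dplyr::pick(dplyr::everything()))) /
                sum(vol_of(dplyr::pick(dplyr::everything()))), .groups = "drop")
  by_z <- map |>
    filter(.data$r_mid >= r_bulk) |>
    group_by(.data$species, .data$z_mid) |>
    summarise(ref_z = sum(.data$density * vol_of(dplyr::pick(dplyr::everything()))) /
                sum(vol_of(dplyr::pick(dplyr::everything()))), .groups = "drop")
  out <- map |>
    left_join(by_z, by = c("species", "z_mid")) |>
    left_join(overall, by = "species") |>
    mutate(ref = ifelse(!is.na(.data$ref_z) & .data$ref_z > 0,
                        .data$ref_z, .data$ref_all),
           ratio = ifelse(.data$ref > 0, .data$density / .data$ref, NA_real_)) |>
    select(-"ref_z", -"ref_all", -"ref")
  out <- tibble::new_tibble(out, class = "relative_density_map")
  attr(out, "r_edges") <- r_edges
  attr(out, "z_edges") <- attr(map, "z_edges")
  attr(out, "n_frames") <- attr(map, "n_frames")
  attr(out, "r_bulk") <- r_bulk
  out
}

#' Radial relative-density profile
#'
#' Volume-weighted average of the relative density over `|z| <= z_window`
#' for each radial bin: the 1D sorting profile along the distance from the
#' pore centre.
#'
#' @param rel A [relative_density()] map.
#' @param z_window Half-height of the averaging window (nm).
#' @return A `radial_profile` tibble: `species`, `r_mid`, `ratio`.
#' @export
radial_profile <- function(rel, z_window = 1.5) {
  if (z_window > max(attr(rel, "z_edges"))) {
    abort("`z_window` exceeds the map height.",
          class = "poremech_validation_error")
  }
  out <- rel |>
    filter(abs(.data$z_mid) <= z_window) |>
    mutate(vol = pi * (.data$r_hi^2 - .data$r_lo^2) * (.data$z_hi - .data$z_lo)) |>
    group_by(.data$species, .data$r_mid) |>
    summarise(ratio = {
      w <- .data$vol[!is.na(.data$ratio)]
      v <- .data$ratio[!is.na(.data$ratio)]
      if (length(v) == 0) NA_real_ else sum(v * w) / sum(w)
    }, .groups = "drop")
  tibble::new_tibble(out, class = "radial_profile")
}

#' Rim enrichment or depletion factors
#'
#' Mean relative density over the rim window
#' `[pore_radius - half_width, pore_radius + half_width]` per species:
#' values above 1 mean the species is enriched at the pore rim, below 1
#' depleted, 0 completely excluded.
#'
#' @param profile A [radial_profile()].
#' @param pore_radius Pore radius (nm).
#' @param half_width Half-width of the rim window (nm).
#' @return A tibble: `species`, `enrichment`.
#' @export
rim_enrichment <- function(profile, pore_radius, half_width = 0.5) {
  sel <- profile$r_mid >= pore_radius - half_width &
    profile$r_mid <= pore_radius + half_width
  if (!any(sel)) {
    abort("rim window contains no radial bins.",
          class = "poremech_validation_error")
  }
  profile[sel, ] |>
    group_by(.data$species) |>
    summarise(enrichment = mean(.data$ratio, na.rm = TRUE), .groups = "drop")
}
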