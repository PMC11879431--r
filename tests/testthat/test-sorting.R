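uniform_frame <- function(n = 5000, box = c(8, 8, 6), seed = 1) {
  withr::with_seed(seed, {
    # a token lipid supplies the midplane; the rest is a uniform gas
    lip <- tibble::tibble(
      x = c(4, 4, 4), y = 4, z = c(4, 3, 3),
      species = "POPC", role = c("head", "tail", "tail"), molecule_id = 1L
    )
    gas <- tibble::tibble(
      x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
      z = runif(n, 0, box[3]),
      species = "GAS", role = "polar", molecule_id = 1L + seq_len(n)
    )
    membrane_frame(dplyr::bind_rows(lip, gas), box = box)
  })
}

test_that("binned mass is conserved exactly", {
  frames <- lapply(1:3, function(s) pore_fix(seed = s))
  dm <- density_map(frames, species = c("POPC", "W"), z_max = 2.0)
  vol <- pi * (dm$r_hi^2 - dm$r_lo^2) * (dm$z_hi - dm$z_lo)
  binned <- sum(dm$density * vol) * attr(dm, "n_frames")
  manual <- sum(vapply(frames, function(fr) {
    ctr <- auto_pore_center(fr)
    mid <- mean(fr$z[fr$role == "tail"])
    box <- frame_box(fr)
    dx <- pmin(abs(fr$x - ctr[1]), box[1] - abs(fr$x - ctr[1]))
    dy <- pmin(abs(fr$y - ctr[2]), box[2] - abs(fr$y - ctr[2]))
    r <- sqrt(dx^2 + dy^2)
    sum(r < max(attr(dm, "r_edges")) & abs(fr$z - mid) < 2.0 &
          fr$species %in% c("POPC", "W"))
  }, numeric(1)))
  expect_equal(binned / manual, 1, tolerance = 1e-9)
})

test_that("uniform particles give a flat density within Poisson bounds", {
  fr <- uniform_frame(n = 20000)
  dm <- density_map(fr, species = "GAS", axis = c(4, 4), z_max = 2)
  vol <- pi * (dm$r_hi^2 - dm$r_lo^2) * (dm$z_hi - dm$z_lo)
  lambda <- 20000 / (8 * 8 * 6) * vol
  counts <- dm$density * vol
  z <- (counts - lambda) / sqrt(lambda)
  expect_gt(mean(abs(z) <= 3), 0.99)
  rel <- relative_density(dm)
  expect_equal(mean(rel$ratio, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("density vanishes beyond the occupied radius", {
  n <- 500
  p <- withr::with_seed(2, tibble::tibble(
    x = 4 + runif(n, -0.45, 0.45), y = 4 + runif(n, -0.45, 0.45),
    z = runif(n, 2, 4), species = "W", role = "water",
    molecule_id = seq_len(n)
  ))
  lip <- tibble::tibble(x = 1, y = 1, z = c(3.5, 3, 2.5), species = "POPC",
                        role = c("head", "tail", "tail"), molecule_id = n + 1L)
  fr <- membrane_frame(dplyr::bind_rows(p, lip), box = c(8, 8, 6))
  dm <- density_map(fr, species = "W", axis = c(4, 4), z_max = 2)
  expect_true(all(dm$density[dm$r_lo >= 0.8] == 0))
})

test_that("averaging identical frames changes nothing", {
  fr <- pore_fix(seed = 9)
  one <- density_map(fr, species = "POPC", axis = c(4, 4))
  two <- density_map(list(fr, fr), species = "POPC", axis = c(4, 4))
  expect_equal(one$density, two$density, tolerance = 1e-12)
})

test_that("radial profiles volume-average the relative map", {
  # ratio 2 in half the z rows and 0 in the other half -> 1.0
  base <- tidyr::expand_grid(species = "X", zi = 1:4, ri = 1:3)
  rel <- tibble::new_tibble(
    dplyr::mutate(base,
                  r_lo = (ri - 1) * 0.5, r_hi = ri * 0.5,
                  z_lo = zi * 0.5 - 1.5, z_hi = zi * 0.5 - 1,
                  r_mid = (r_lo + r_hi) / 2, z_mid = (z_lo + z_hi) / 2,
                  density = 1, ratio = ifelse(zi <= 2, 2, 0)),
    class = "relative_density_map"
  )
  attr(rel, "z_edges") <- seq(-1, 1, by = 0.5)
  prof <- radial_profile(rel, z_window = 1)
  expect_equal(prof$ratio, rep(1, 3))
})

test_that("monotone maps stay monotone after z averaging", {
  base <- tidyr::expand_grid(species = "X", zi = 1:4, ri = 1:6)
  rel <- tibble::new_tibble(
    dplyr::mutate(base,
                  r_lo = (ri - 1) * 0.5, r_hi = ri * 0.5,
                  z_lo = zi * 0.5 - 1.25, z_hi = zi * 0.5 - 0.75,
                  r_mid = (r_lo + r_hi) / 2, z_mid = (z_lo + z_hi) / 2,
                  density = 1, ratio = ri + 0.1 * zi),
    class = "relative_density_map"
  )
  attr(rel, "z_edges") <- seq(-1, 1, by = 0.5)
  prof <- radial_profile(rel, z_window = 1)
  expect_true(all(diff(prof$ratio) > 0))
})

test_that("rim enrichment ratios recover generator factors against a neutral species", {
  frames <- lapply(1:20, function(s) {
    make_pore_membrane(200, c(POPC = 0.6, LPC = 0.2, CHOL = 0.2), box_xy = 11,
                       d_hc = 2.8, pore_radius = 1.0,
                       rim_enrichment = c(LPC = 2, CHOL = 0), seed = 100 + s)
  })
  prof <- radial_profile(relative_density(
    density_map(frames, species = c("POPC", "LPC", "CHOL"))), z_window = 1.4)
  enr <- rim_enrichment(prof, pore_radius = 1.0)
  e <- setNames(enr$enrichment, enr$species)
  expect_equal(unname(e["CHOL"]), 0, tolerance = 0.05)
  expect_gt(e["LPC"], 1)
  # the ratio to the neutral species removes the rim-geometry factor:
  # (f_LPC * 2 / Z) / f_LPC over (f_POPC / Z) / f_POPC = 2
  expect_equal(unname(e["LPC"] / e["POPC"]), 2, tolerance = 0.2 / 2)
})

test_that("maps are covariant under joint translation of frames and axis", {
  fr <- pore_fix(seed = 14)
  box <- frame_box(fr)
  ctr <- attr(fr, "pore_center")
  m1 <- density_map(fr, species = "W", axis = ctr)
  moved <- as.data.frame(fr)
  moved$x <- moved$x + 2.3
  moved$y <- moved$y + 1.1
  fr2 <- membrane_frame(moved, box)
  m2 <- density_map(fr2, species = "W",
                    axis = (ctr + c(2.3, 1.1)) %% box[1:2])
  expect_equal(m1$density, m2$density, tolerance = 1e-9)
})

test_that("bulk validation errors surface", {
  fr <- pore_fix(seed = 15)
  dm <- density_map(fr, species = "W", axis = attr(fr, "pore_center"))
  expect_error(relative_density(dm, r_bulk = 10),
               class = "poremech_validation_error")
  prof <- radial_profile(relative_density(dm), z_window = 1.4)
  expect_error(rim_enrichment(prof, pore_radius = 50),
               class = "poremech_validation_error")
})
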