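make_tilted_lipid <- function(theta, phi = 0, upper = TRUE, mol = 1L,
                              x = 2.5, y = 2.5) {
  s <- if (upper) 1 else -1
  d <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), s * cos(theta))
  head_z <- if (upper) 4 else 2
  tibble::tibble(
    x = c(x, x - d[1]), y = c(y, y - d[2]),
    z = c(head_z, head_z - d[3]),
    species = "POPC", role = c("head", "tail"), molecule_id = mol
  )
}

test_that("tilt vectors follow t = d/(n.d) - n", {
  up <- make_tilted_lipid(0, mol = 1L)
  tilted <- make_tilted_lipid(pi / 6, mol = 2L, x = 1.0)
  low <- make_tilted_lipid(0, upper = FALSE, mol = 3L, x = 4)
  fr <- membrane_frame(dplyr::bind_rows(up, tilted, low), box = c(5, 5, 6))
  df <- compute_directors(fr)
  t_up <- df[df$molecule_id == 1, ]
  expect_equal(c(t_up$tx, t_up$ty), c(0, 0), tolerance = 1e-12)
  t30 <- df[df$molecule_id == 2, ]
  expect_equal(sqrt(t30$tx^2 + t30$ty^2), tan(pi / 6), tolerance = 1e-9)
  expect_equal(df$leaflet, c("upper", "upper", "lower"))
})

test_that("mirroring the frame in z swaps the leaflet tilt populations", {
  fr <- flat_fix(seed = 10)
  df <- compute_directors(fr)
  mir <- as.data.frame(fr)
  mir$z <- frame_box(fr)[3] - mir$z
  df_m <- compute_directors(membrane_frame(mir, frame_box(fr)))
  a <- sort(round(df$tx[df$leaflet == "upper"], 9))
  b <- sort(round(df_m$tx[df_m$leaflet == "lower"], 9))
  expect_equal(a, b)
})

test_that("nearly in-plane lipids are excluded and counted", {
  ok <- make_tilted_lipid(0.1, mol = 1L)
  flatone <- make_tilted_lipid(pi / 2 - 0.01, mol = 2L, x = 1)
  fr <- membrane_frame(dplyr::bind_rows(ok, flatone), box = c(5, 5, 6))
  df <- compute_directors(fr)
  expect_equal(nrow(df), 1)
  expect_equal(attr(df, "n_excluded"), 1)
})

test_that("the tilt modulus estimator inverts the Boltzmann sampler", {
  for (kt in c(42.53, 166)) {
    t <- sample_tilt_vectors(kt, 0.64, 1e5, seed = round(kt))
    est <- estimate_tilt_modulus(t, area_per_lipid = 0.64)
    expect_equal(est$kappa_theta, kt, tolerance = 0.05)
  }
  # small n: looser recovery
  t <- sample_tilt_vectors(42.53, 0.64, 500, seed = 99)
  est <- estimate_tilt_modulus(t, area_per_lipid = 0.64)
  expect_equal(est$kappa_theta, 42.53, tolerance = 0.2)
})

test_that("degenerate tilt input raises a singular-estimate error", {
  t <- tibble::tibble(tx = rep(0, 600), ty = rep(0, 600))
  expect_error(estimate_tilt_modulus(t, area_per_lipid = 0.64),
               class = "poremech_singular_error")
  expect_error(estimate_tilt_modulus(tibble::tibble(tx = rnorm(100),
                                                    ty = rnorm(100)),
                                     area_per_lipid = 0.64),
               class = "poremech_validation_error")
})

test_that("the bending modulus estimator inverts the splay sampler", {
  for (k in c(33.7, 105)) {
    s <- sample_splay_values(k, 0.64, 1e5, seed = round(k))
    est <- estimate_bending_modulus(s, area_per_lipid = 0.64)
    expect_equal(est$kappa, k, tolerance = 0.05)
  }
  expect_error(estimate_bending_modulus(rep(0.1, 2e4), area_per_lipid = 0.64),
               class = "poremech_singular_error")
  expect_error(estimate_bending_modulus(rnorm(100), area_per_lipid = 0.64),
               class = "poremech_validation_error")
})

test_that("moduli estimates scale linearly with the temperature input", {
  t <- sample_tilt_vectors(50, 0.64, 2e4, temperature = 310, seed = 5)
  k300 <- estimate_tilt_modulus(t, 0.64, temperature = 300)$kappa_theta
  k310 <- estimate_tilt_modulus(t, 0.64, temperature = 310)$kappa_theta
  k320 <- estimate_tilt_modulus(t, 0.64, temperature = 320)$kappa_theta
  expect_equal(k310 / k300, 310 / 300, tolerance = 1e-9)
  expect_equal(k320 / k310, 320 / 310, tolerance = 1e-9)
})

test_that("estimators are invariant to frame translation and lipid order", {
  fr <- flat_fix(seed = 12)
  df1 <- compute_directors(fr)
  moved <- as.data.frame(fr)
  moved$x <- moved$x + 1.7
  moved$y <- moved$y + 0.9
  df2 <- compute_directors(membrane_frame(moved, frame_box(fr)))
  shuffled <- as.data.frame(fr)[sample(nrow(fr)), ]
  df3 <- compute_directors(membrane_frame(shuffled, frame_box(fr)))
  expect_equal(sort(df1$tx), sort(df2$tx), tolerance = 1e-9)
  expect_equal(sort(df1$tx), sort(df3$tx), tolerance = 1e-9)
})

test_that("spontaneous curvature recovers the stress-profile ground truth", {
  sp <- make_stress_profile(J_s = 0.172, kappa = 42.8, d_hc = 2.85)
  expect_equal(spontaneous_curvature(sp, kappa = 42.8), 0.172,
               tolerance = 1e-3 / 0.172)
  # scaling the stress doubles the recovered curvature
  sp2 <- sp
  sp2$s <- 2 * sp2$s
  expect_equal(spontaneous_curvature(sp2, kappa = 42.8), 2 * 0.172,
               tolerance = 1e-3)
  # both leaflets agree in sign
  expect_equal(spontaneous_curvature(sp, 42.8, leaflet = "lower"), 0.172,
               tolerance = 1e-3)
  expect_error(spontaneous_curvature(sp, 42.8, pivot = 5),
               class = "poremech_validation_error")
})

test_that("hydrophobic thickness recovers the built core thickness", {
  expect_equal(hydrophobic_thickness(flat_fix(seed = 2, d_hc = 2.8)), 2.8,
               tolerance = 0.15 / 2.8)
  expect_equal(hydrophobic_thickness(flat_fix(seed = 3, d_hc = 3.4)), 3.4,
               tolerance = 0.15 / 3.4)
  dry <- flat_fix(seed = 4)
  dry <- membrane_frame(as.data.frame(dry)[dry$role != "water", ],
                        frame_box(dry))
  expect_error(hydrophobic_thickness(dry), class = "poremech_degenerate_error")
})
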