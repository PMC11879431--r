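test_that("hkh_energy evaluates the closed forms for simple patches", {
  expect_equal(hkh_energy(flat_patch(100), kappa = 33.7), 0)
  # spherical cap: A * kappa/2 * (2/r)^2 = 100 * 16.85 * 0.04 = 67.4
  expect_equal(hkh_energy(spherical_cap_surface(radius = 10, area = 100),
                          kappa = 33.7), 67.4, tolerance = 1e-9)
  # uniform tilt: A * kappa_theta/2 * t^2 = 50 * 21.265 * 0.09
  expect_equal(hkh_energy(flat_patch(50, tilt = 0.3), kappa = 1,
                          kappa_theta = 42.53), 50 * 42.53 / 2 * 0.09,
               tolerance = 1e-9)
  # leaflet_factor rescales only the tilt term
  expect_equal(hkh_energy(flat_patch(50, tilt = 0.3), kappa = 1,
                          kappa_theta = 42.53, leaflet_factor = 0.5),
               50 * 42.53 / 4 * 0.09, tolerance = 1e-9)
})

test_that("hkh_energy reduces to plain Helfrich bending for t = 0, kappa_bar = 0", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(16:64, 1)
    surf <- tibble::tibble(dA = runif(n, 0.01, 2), H = rnorm(n, 0, 0.5),
                           K_G = rnorm(n, 0, 0.2), tilt = 0)
    kappa <- runif(1, 20, 110)
    J_s <- runif(1, -0.2, 0.25)
    expect_equal(hkh_energy(surf, kappa = kappa, J_s = J_s),
                 helfrich_oracle(surf, kappa, J_s),
                 tolerance = 1e-10)
  }
})

test_that("the closed-form rim line tension matches hand evaluations", {
  # kappa = 33.7, J_s = 0, d_hc = 2.85: pi * 33.7/2.85 = 37.15 kJ/mol/nm
  expect_equal(helfrich_line_tension(33.7, 2.85), 61.7, tolerance = 1e-3)
  # POPG-like inputs
  expect_equal(helfrich_line_tension(30.2, 2.6, 0.227), 30.1, tolerance = 1e-3)
  # curvature matching cancels the rim penalty
  expect_equal(helfrich_line_tension(40, 2.8, J_s = 2 / 2.8), 0)
  expect_error(helfrich_line_tension(40, -1), class = "poremech_validation_error")
})

test_that("the rim penalty decreases with J_s below the matching curvature", {
  d <- 2.8
  js <- seq(-0.3, 2 / d - 0.01, length.out = 40)
  g <- helfrich_line_tension(33.7, d, js)
  expect_true(all(diff(g) < 0))
})

test_that("rim quadrature converges to the closed form for wide pores", {
  set.seed(11)
  for (i in 1:20) {
    kappa <- runif(1, 28.2, 105)
    d_hc <- runif(1, 2.6, 3.4)
    J_s <- runif(1, -0.178, 0.227)
    q <- rim_quadrature_line_tension(kappa, d_hc, J_s, pore_radius = 100 * d_hc)
    expect_equal(q / helfrich_line_tension(kappa, d_hc, J_s), 1,
                 tolerance = 0.005)
  }
  # tight pores stay finite and the result is linear in kappa
  tight <- rim_quadrature_line_tension(33.7, 2.8, 0, pore_radius = 2.8)
  expect_true(is.finite(tight))
  expect_equal(rim_quadrature_line_tension(67.4, 2.8, 0, pore_radius = 28),
               2 * rim_quadrature_line_tension(33.7, 2.8, 0, pore_radius = 28),
               tolerance = 1e-12)
})

test_that("classical nucleation theory energies and barrier position", {
  expect_equal(cnt_energy(0, 40), 0)
  expect_equal(cnt_energy(1, 40), 151.3, tolerance = 1e-3)  # 2*pi*40 pN nm
  # with sigma > 0 the maximum sits at R* = gamma/sigma
  R <- seq(0, 20, by = 0.01)
  e <- cnt_energy(R, gamma = 40, sigma = 5)
  expect_equal(R[which.max(e)], 40 / 5, tolerance = 0.01)
  expect_error(cnt_energy(-1, 40), class = "poremech_validation_error")
})

test_that("area rescaling follows dG - kT log(area ratio)", {
  expect_equal(rescale_nucleation_energy(90, 83, 83), 90)
  kT <- 0.00831446 * 310
  expect_equal(rescale_nucleation_energy(90, 2 * 83, 83), 90 - kT * log(2),
               tolerance = 1e-9)
  expect_equal(kT * log(2), 1.787, tolerance = 1e-3)
  expect_equal(rescale_nucleation_energy(90, 1e9, 83), 48.0, tolerance = 0.3 / 48)
  expect_error(rescale_nucleation_energy(90, -1, 83),
               class = "poremech_validation_error")
})

test_that("pore probabilities and stability factors report floor-log10 orders", {
  p0 <- pore_probability(0)
  expect_equal(p0$probability, 1)
  expect_equal(p0$order, 0)
  p48 <- pore_probability(48)
  expect_equal(p48$probability, 8.2e-9, tolerance = 0.01)
  expect_equal(p48$order, -9)
  s80 <- stability_factor(80)
  expect_equal(s80$factor, 3.0e13, tolerance = 0.01)
  expect_equal(s80$order, 13)
  # huge barriers do not underflow the order
  expect_equal(pore_probability(8000)$order, floor(-8000 / (0.00831446 * 310 * log(10))))
})

test_that("rescaling and pore probability compose linearly in area", {
  areas <- 10^(3:9)
  p <- pore_probability(rescale_nucleation_energy(90, areas, 83))$probability
  ratios <- p / p[1]
  expect_equal(ratios, areas / areas[1], tolerance = 1e-9)
})

test_that("unit conversions round-trip", {
  x <- c(0.001, 1, 37.15, 1e4)
  expect_equal(pn_to_kj_mol_nm(kj_mol_nm_to_pn(x)), x, tolerance = 1e-12)
  expect_equal(kj_mol_nm_to_pn(1), 1.66054, tolerance = 1e-9)
})

test_that("correlation analysis honours exclusions and degenerate input", {
  d <- tibble::tibble(m = c("a", "b", "c", "d"), x = c(1, 2, 3, 4),
                      y = c(2, 4, 6, 100))
  out <- correlate_membranes(d, x, y, label = m, exclude = "d")
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$slope, 2, tolerance = 1e-12)
  expect_equal(out$n, 3)
  expect_equal(correlate_membranes(d[1:3, ], x, -x)$r, -1, tolerance = 1e-12)
  # hand-computed Pearson r for a slightly off-line triple
  d2 <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6.1))
  r_hand <- 4.1 / sqrt(2 * (2.0333333^2 + 0.0333333^2 + 2.0666667^2))
  expect_equal(correlate_membranes(d2, x, y)$r, r_hand, tolerance = 1e-6)
  expect_error(correlate_membranes(d, x, y, label = m,
                                   exclude = c("a", "b")),
               class = "poremech_validation_error")
})

test_that("the reference parameter table supports the correlation workflow", {
  tab <- reference_elastic_parameters()
  expect_equal(nrow(tab), 9)
  out <- correlate_membranes(tab, kappa, kappa_theta, label = label,
                             exclude = "POPC:CHOL 70:30")
  expect_equal(out$n, 8)
  expect_gt(out$r, 0.9)  # bending and tilt stiffness move together
})
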