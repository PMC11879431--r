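test_that("read_pmf parses XVG comments, CSV and an SE column", {
  xi <- seq(0.2, 6.5, by = 0.3)
  G <- 10 * (xi - 0.25)^2 - 3
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# created by some tool", "@    title \"PMF\"",
               "@ s0 legend \"G\"", paste(xi, G)), path)
  pmf <- read_pmf(path)
  expect_s3_class(pmf, "pmf_profile")
  expect_equal(nrow(pmf), length(xi))
  # the xi = 0.25-ish minimum (G = -3) is anchored to zero
  expect_equal(min(pmf$G[pmf$xi < 0.5]), 0, tolerance = 1e-9)

  pcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("xi,G,se", paste(xi, G, 0.5, sep = ",")), pcsv)
  pmf3 <- read_pmf(pcsv)
  expect_true("se" %in% names(pmf3))
  expect_equal(pmf3$se, rep(0.5, length(xi)))
})

test_that("read_pmf rejects short or duplicated tables", {
  p <- withr::local_tempfile()
  writeLines(paste(1:5, 1:5), p)
  expect_error(read_pmf(p), class = "poremech_validation_error")
  writeLines(paste(c(1:10, 10), c(1:10, 11)), p)
  expect_error(read_pmf(p), class = "poremech_validation_error")
})

test_that("nucleation free energy interpolates linearly at the wire state", {
  pmf <- make_synthetic_pmf(40, 90, noise_sd = 0)
  expect_equal(nucleation_free_energy(pmf), 90, tolerance = 1e-6)
  expect_equal(nucleation_free_energy(make_synthetic_pmf(100, 180, noise_sd = 0)),
               180, tolerance = 1e-6)
  # hand-built two-point bracket: G(0.90) = 88, G(0.94) = 92 -> 90 at 0.92
  hand <- pmf_profile(xi = c(0.90, 0.94, 2, 3), G = c(88, 92, 95, 96))
  expect_equal(nucleation_free_energy(hand), 90)
  expect_error(nucleation_free_energy(hand, xi_nuc = 0.5),
               class = "poremech_range_error")
})

test_that("line tension recovers the generator's ground truth exactly without noise", {
  expect_equal(line_tension(make_synthetic_pmf(40, 90, noise_sd = 0))$gamma_pn,
               40, tolerance = 0.01 / 40)
  expect_equal(line_tension(make_synthetic_pmf(100, 180, noise_sd = 0))$gamma_pn,
               100, tolerance = 0.01 / 100)
})

test_that("a slope of 60.54 kJ/mol per xi unit is 40 pN at R0 = 0.4", {
  xi <- seq(0.2, 6.5, by = 0.05)
  pmf <- pmf_profile(xi, 60.54113 * xi, R0 = 0.4)
  lt <- line_tension(pmf)
  expect_equal(lt$gamma_pn, 40, tolerance = 1e-5)
  # unit sanity: gamma in pN converted back equals slope/(2 pi) in kJ/mol/nm
  expect_equal(pn_to_kj_mol_nm(lt$gamma_pn), lt$slope_kj_mol_nm / (2 * pi),
               tolerance = 1e-9)
  expect_equal(0.602214 * 1.66054, 1, tolerance = 1e-6)
  # the slope-is-gamma convention skips the 2 pi factor
  expect_equal(line_tension(pmf, slope_is_gamma = TRUE)$gamma_pn,
               lt$gamma_pn * 2 * pi, tolerance = 1e-9)
})

test_that("line tension flags poor fits and short windows", {
  xi <- seq(0.2, 6.5, by = 0.05)
  set.seed(1)
  bumpy <- pmf_profile(xi, sin(xi * 4) * 20 + xi)
  expect_true(line_tension(bumpy)$low_r2)
  expect_error(line_tension(pmf_profile(c(0.2, 1, 2, 4.1, 6.6),
                                        c(0, 1, 2, 3, 4))),
               class = "poremech_validation_error")
})

test_that("estimates are invariant under adding a constant to G", {
  pmf <- make_synthetic_pmf(55, 120, noise_sd = 0)
  up <- pmf
  up$G <- up$G + 123.4
  expect_equal(nucleation_free_energy(up), nucleation_free_energy(pmf),
               tolerance = 1e-9)
  expect_equal(line_tension(up)$gamma_pn, line_tension(pmf)$gamma_pn,
               tolerance = 1e-12)
})

test_that("metastable wells are detected with their depth, ripples suppressed", {
  meta <- detect_metastable(make_synthetic_pmf(25, 60, metastable_depth = 5,
                                               noise_sd = 0))
  expect_equal(nrow(meta), 1)
  expect_equal(meta$xi_min, 2.5, tolerance = 0.06)
  expect_equal(meta$depth, 5, tolerance = 0.05)
  expect_equal(nrow(detect_metastable(make_synthetic_pmf(70, 130, noise_sd = 0))), 0)
  expect_equal(nrow(detect_metastable(
    make_synthetic_pmf(25, 60, metastable_depth = 0.5, noise_sd = 0))), 0)
})

test_that("identical noiseless replicates give zero bootstrap SEs", {
  pmf <- make_synthetic_pmf(40, 90, noise_sd = 0)
  reps <- replicate(20, pmf, simplify = FALSE)
  bo <- bootstrap_errors(reps, n_boot = 50, seed = 1)
  expect_equal(bo$std.error, c(0, 0), tolerance = 1e-12)
  expect_error(bootstrap_errors(pmf, n_boot = 20),
               class = "poremech_validation_error")
})

test_that("residual-bootstrap gamma SE brackets the analytic OLS slope SE", {
  pmf <- make_synthetic_pmf(40, 90, noise_sd = 2, seed = 3)
  bo <- bootstrap_errors(pmf, n_boot = 200, seed = 4)
  sel <- pmf$xi >= 4 & pmf$xi <= 6.5
  R <- pmf$xi[sel] * 0.4
  analytic <- 2 / (sd(R) * sqrt(sum(sel))) / (2 * pi) * 1.66054
  expect_gt(bo$std.error[2], 0.5 * analytic)
  expect_lt(bo$std.error[2], 2 * analytic)
  expect_identical(bo, bootstrap_errors(pmf, n_boot = 200, seed = 4))
})

test_that("hysteresis measures the maximal anchored profile gap", {
  a <- make_synthetic_pmf(40, 90, noise_sd = 0)
  expect_equal(hysteresis(a, a), 0)
  b <- a
  b$G <- b$G + ifelse(b$xi > 1, 3, 0)
  expect_equal(hysteresis(a, b), 3, tolerance = 1e-9)
  # shifted grids interpolate without error
  c <- make_synthetic_pmf(40, 90, noise_sd = 0,
                          xi_grid = sort(c(seq(0.18, 6.6, by = 0.07), 0.92)))
  expect_lt(hysteresis(a, c), 1)
  short <- pmf_profile(c(8, 9, 10), c(0, 1, 2))
  expect_error(hysteresis(a, short), class = "poremech_validation_error")
})

test_that("fit_pore_energetics bundles estimates with tidy/glance methods", {
  fit <- fit_pore_energetics(make_synthetic_pmf(40, 90, noise_sd = 0))
  td <- tidy(fit)
  expect_equal(td$estimate, c(90, 40), tolerance = 1e-3)
  expect_equal(td$term, c("dG_nuc", "gamma"))
  gl <- glance(fit)
  expect_gt(gl$r_squared, 0.999)
  expect_equal(gl$n_metastable, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("noisy round trips recover truth within one percent of scale", {
  pmf <- make_synthetic_pmf(60, 140, noise_sd = 0,
                            xi_grid = sort(c(seq(0.2, 7, by = 0.04), 0.92)))
  expect_equal(nucleation_free_energy(pmf) / 140, 1, tolerance = 0.01)
  expect_equal(line_tension(pmf)$gamma_pn / 60, 1, tolerance = 0.01)
})
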