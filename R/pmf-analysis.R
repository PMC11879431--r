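#' Read a PMF from an XVG-compatible or CSV text file
#'
#' Parses a two- or three-column numeric table of (xi, free energy in
#' kJ/mol, optional per-point SE).  Lines starting with `#` or `@` (XVG
#' comments and legends) are skipped; comma- or whitespace-separated values
#' are both accepted.  The profile is sorted by `xi` and anchored so that
#' its baseline over `xi < 0.5` becomes zero (see [nucleation_free_energy()]
#' for how the baseline is defined for noisy profiles).
#'
#' @param path Path to the file.
#' @param R0 Nucleated-pore radius (nm) attached to the profile.
#' @return A [pmf_profile()].
#' @export
read_pmf <- function(path, R0 = 0.4) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "poremech_validation_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  # drop a header line if the first row is not numeric
  if (length(lines) > 0 && is.na(suppressWarnings(
    as.numeric(strsplit(trimws(lines[1]), "[,[:space:]]+")[[1]][1])))) {
    lines <- lines[-1]
  }
  d <- tryCatch(
    read.table(text = gsub(",", " ", lines), header = FALSE),
    error = function(e) abort("could not parse numeric columns.",
                              class = "poremech_validation_error")
  )
  if (ncol(d) < 2) {
    abort("need at least two numeric columns (xi, G).",
          class = "poremech_validation_error")
  }
  if (nrow(d) < 10) {
    abort("a PMF needs at least 10 points.", class = "poremech_validation_error")
  }
  if (anyDuplicated(d[[1]])) {
    abort("duplicated xi values.", class = "poremech_validation_error")
  }
  ord <- order(d[[1]])
  se <- if (ncol(d) >= 3) d[[3]][ord] else NULL
  pmf <- pmf_profile(d[[1]][ord], d[[2]][ord], se = se, R0 = R0)
  anchor_pmf(pmf)
}

#' Write a profile as XVG-compatible text
#'
#' @param data A data frame whose first columns are numeric (e.g. a
#'   [pmf_profile()] or [make_stress_profile()] output).
#' @param path Output path.
#' @param title Title written as an `@` comment line.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(data, path, title = "poremech profile") {
  num <- data[vapply(data, is.numeric, logical(1))]
  header <- c(sprintf("@    title \"%s\"", title),
              sprintf("# columns: %s", paste(names(num), collapse = " ")))
  body <- do.call(paste, c(unname(lapply(num, format, digits = 10))))
  writeLines(c(header, body), path)
  invisible(path)
}

# Baseline of a PMF over xi < 0.5.  For noise-free data this is the raw
# minimum; for noisy data the pointwise minimum is biased low, so the
# baseline is taken from a smoothing-spline fit to the nucleation branch.
pmf_baseline <- function(pmf) {
  low <- pmf$xi < 0.5
  if (!any(low)) return(0)
  noise <- estimate_point_noise(pmf$G)
  if (noise < 1e-8 || sum(low) < 4) return(min(pmf$G[low]))
  branch <- pmf$xi < 0.92
  if (sum(branch) >= 10) {
    fit <- smooth.spline(pmf$xi[branch], pmf$G[branch])
    min(predict(fit, pmf$xi[low])$y)
  } else {
    min(pmf$G[low])
  }
}

#' Anchor a PMF at its flat-membrane baseline
#'
#' Shifts the profile so the baseline over `xi < 0.5` is zero.  Profiles
#' without points below `xi = 0.5` are assumed pre-anchored and returned
#' unchanged.
#'
#' @param pmf A [pmf_profile()].
#' @return The shifted [pmf_profile()].
#' @export
anchor_pmf <- function(pmf) {
  b <- pmf_baseline(pmf)
  pmf$G <- pmf$G - b
  pmf
}

#' Pore nucleation free energy
#'
#' The free energy of the thin-water-wire state: the PMF interpolated
#' linearly at `xi_nuc` (default 0.92), measured from the flat-membrane
#' baseline so that the value is invariant under adding a constant to the
#' profile.
#'
#' @param pmf A [pmf_profile()].
#' @param xi_nuc Coordinate value of the nucleated state.
#' @return Nucleation free energy in kJ/mol.
#' @export
nucleation_free_energy <- function(pmf, xi_nuc = 0.92) {
  if (xi_nuc < min(pmf$xi) || xi_nuc > max(pmf$xi)) {
    abort("`xi_nuc` lies outside the profile range.",
          class = "poremech_range_error")
  }
  approx(pmf$xi, pmf$G, xout = xi_nuc)$y - pmf_baseline(pmf)
}

#' Rim line tension from the linear expansion regime of a PMF
#'
#' Fits ordinary least squares of G against pore radius `R = xi * R0` over
#' the fit range (default `4 <= xi <= 6.5`).  The slope of the free energy
#' with radius for a wide pore is \eqn{2\pi\gamma}, so the line tension is
#' the slope divided by \eqn{2\pi}, converted from kJ mol^-1 nm^-1 to pN.
#' Setting `slope_is_gamma = TRUE` reports the raw slope as the tension
#' instead (no \eqn{2\pi}), for comparison with conventions that identify
#' the slope itself with the line tension.
#'
#' @param pmf A [pmf_profile()].
#' @param fit_range Two xi values bounding the fit window.
#' @param slope_is_gamma If `TRUE`, skip the \eqn{2\pi} factor.
#' @return A one-row tibble: `gamma_pn`, `gamma_kj_mol_nm`, `slope_kj_mol_nm`
#'   (dG/dR), `intercept`, `r_squared`, `n_points`, `low_r2` (diagnostic
#'   flag, `TRUE` when r^2 < 0.9).
#' @export
line_tension <- function(pmf, fit_range = c(4, 6.5), slope_is_gamma = FALSE) {
  R0 <- pmf_R0(pmf)
  sel <- pmf$xi >= fit_range[1] & pmf$xi <= fit_range[2]
  if (sum(sel) < 5) {
    abort("need at least 5 grid points inside the fit range.",
          class = "poremech_validation_error")
  }
  R <- pmf$xi[sel] * R0
  G <- pmf$G[sel]
  fit <- lm(G ~ R)
  slope <- unname(coef(fit)[2])
  sst <- sum((G - mean(G))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  gamma_kj <- if (slope_is_gamma) slope else slope / (2 * pi)
  tibble(
    gamma_pn = kj_mol_nm_to_pn(gamma_kj),
    gamma_kj_mol_nm = gamma_kj,
    slope_kj_mol_nm = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_points = sum(sel),
    low_r2 = r2 < 0.9
  )
}

#' Detect metastable open pores in a PMF
#'
#' Searches the expansion branch (`xi > 1`) for local free-energy minima: a
#' metastable pore shows up as a well whose depth to the lower flanking
#' maximum exceeds `max(min_depth, 2 * SE)` (the per-point SE column, when
#' present).  Noisy profiles are smoothed with a cross-validated smoothing
#' spline before extremum detection; noise-free profiles are used as is.
#'
#' @param pmf A [pmf_profile()].
#' @param min_depth Minimum reportable well depth in kJ/mol.
#' @return A tibble with columns `xi_min` and `depth` (kJ/mol), zero rows
#'   when no metastable pore is present.
#' @export
detect_metastable <- function(pmf, min_depth = 1.0) {
  se <- if ("se" %in% names(pmf)) median(pmf$se) else NA_real_
  threshold <- max(min_depth, if (is.finite(se)) 2 * se else 0)
  noise <- estimate_point_noise(pmf$G)
  y <- pmf$G
  # Denoise with a centred running mean before extremum detection.  Unlike a
  # spline, a running mean preserves monotonicity, so it cannot fabricate
  # local minima from lack of fit at the plateau-to-linear crossover; a
  # metastable well (~1 coordinate unit wide) survives the 0.35-unit window
  # nearly unattenuated.
  if (noise > 1e-8 && nrow(pmf) >= 30) {
    half <- max(1L, as.integer(round(0.35 / stats::median(diff(pmf$xi)))))
    y <- running_mean(y, half)
  }
  sel <- which(pmf$xi > 1)
  if (length(sel) < 3) return(tibble(xi_min = numeric(0), depth = numeric(0)))
  ys <- y[sel]
  xs <- pmf$xi[sel]
  n <- length(ys)
  is_min <- c(FALSE, ys[2:(n - 1)] < ys[1:(n - 2)] &
                ys[2:(n - 1)] <= ys[3:n], FALSE)
  idx <- which(is_min)
  out <- purrr::map_dfr(idx, function(i) {
    left <- max(ys[1:i])
    right <- max(ys[i:n])
    tibble(xi_min = xs[i], depth = min(left, right) - ys[i])
  })
  if (nrow(out) == 0) return(tibble(xi_min = numeric(0), depth = numeric(0)))
  # merge shallow ripples: keep wells meeting the depth threshold
  out <- out[out$depth >= threshold, , drop = FALSE]
  arrange(out, .data$xi_min)
}

#' Bootstrap standard errors for nucleation free energy and line tension
#'
#' With `M >= 3` replicate profiles, a case bootstrap over replicates:
#' profiles are resampled with replacement, averaged on the first profile's
#' grid, and re-analysed.  With a single profile, a residual bootstrap: a
#' smoothing spline captures the profile shape, residuals are resampled with
#' replacement onto the fitted curve, and both estimators are re-run.
#'
#' @param pmf A [pmf_profile()], or a list of replicate profiles.
#' @param n_boot Number of bootstrap draws (>= 50).
#' @param seed Integer seed.
#' @param xi_nuc,fit_range Passed to the estimators.
#' @return A tibble with columns `term` (`"dG_nuc"`, `"gamma_pn"`),
#'   `estimate` and `std.error`.
#' @export
bootstrap_errors <- function(pmf, n_boot = 200, seed = NULL, xi_nuc = 0.92,
                             fit_range = c(4, 6.5)) {
  if (n_boot < 50) {
    abort("`n_boot` must be >= 50.", class = "poremech_validation_error")
  }
  replicated <- is.list(pmf) && !is.data.frame(pmf)
  if (replicated && length(pmf) < 3) {
    abort("need >= 3 replicate profiles for the case bootstrap.",
          class = "poremech_validation_error")
  }

  estimate_both <- function(p) {
    c(nucleation_free_energy(p, xi_nuc),
      line_tension(p, fit_range)$gamma_pn)
  }

  if (replicated) {
    grid <- pmf[[1]]$xi
    R0 <- pmf_R0(pmf[[1]])
    mat <- vapply(pmf, function(p) approx(p$xi, p$G, xout = grid)$y,
                  numeric(length(grid)))
    point <- estimate_both(pmf_profile(grid, rowMeans(mat), R0 = R0))
    reps <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(ncol(mat), ncol(mat), replace = TRUE)
        estimate_both(pmf_profile(grid, rowMeans(mat[, pick, drop = FALSE]),
                                  R0 = R0))
      }, numeric(2))
    })
  } else {
    sel <- pmf$xi >= fit_range[1] & pmf$xi <= fit_range[2]
    if (sum(sel) < 20) {
      abort("need >= 20 points in the fit range for the residual bootstrap.",
            class = "poremech_validation_error")
    }
    # Trend by a short running mean; residuals rescaled so their spread
    # matches a robust differencing estimate of the point noise, which is
    # insensitive to the smoothing bias of the trend (a curved trend would
    # otherwise inflate, and an overfitted one deflate, the resampled noise).
    fitted <- running_mean(pmf$G, 2L)
    res <- pmf$G - fitted
    res <- res - mean(res)
    sigma_hat <- estimate_point_noise(pmf$G)
    if (sd(res) > 0) res <- res * (sigma_hat / sd(res))
    point <- estimate_both(pmf)
    R0 <- pmf_R0(pmf)
    reps <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        Gb <- fitted + sample(res, length(res), replace = TRUE)
        estimate_both(pmf_profile(pmf$xi, Gb, R0 = R0))
      }, numeric(2))
    })
  }
  tibble(
    term = c("dG_nuc", "gamma_pn"),
    estimate = point,
    std.error = apply(reps, 1, sd)
  )
}

#' Hysteresis between opening and closing profiles
#'
#' Maximum absolute free-energy difference between two profiles of the same
#' process over their common coordinate range, after both are anchored at
#' their flat-membrane baseline.  Profiles on different grids are compared
#' by linear interpolation.
#'
#' @param pmf_open,pmf_close Two [pmf_profile()]s with overlapping ranges.
#' @return Maximum absolute deviation in kJ/mol.
#' @export
hysteresis <- function(pmf_open, pmf_close) {
  lo <- max(min(pmf_open$xi), min(pmf_close$xi))
  hi <- min(max(pmf_open$xi), max(pmf_close$xi))
  if (lo >= hi) {
    abort("profiles do not overlap in xi.", class = "poremech_validation_error")
  }
  a <- anchor_pmf(pmf_open)
  b <- anchor_pmf(pmf_close)
  sel <- a$xi >= lo & a$xi <= hi
  gb <- approx(b$xi, b$G, xout = a$xi[sel])$y
  max(abs(a$G[sel] - gb))
}

#' Fit the pore energetics of a PMF
#'
#' One-stop analysis of a free-energy profile: nucleation free energy at
#' `xi_nuc`, rim line tension from the linear regime, metastable-pore
#' detection, and (optionally) bootstrap standard errors.
#'
#' @inheritParams bootstrap_errors
#' @param min_depth Metastability depth threshold (kJ/mol).
#' @return A `pore_energetics` object with [generics::tidy()] /
#'   [generics::glance()] methods and an `autoplot()`.
#' @examples
#' fit <- fit_pore_energetics(make_synthetic_pmf(40, 90, noise_sd = 0))
#' tidy(fit)
#' @export
fit_pore_energetics <- function(pmf, xi_nuc = 0.92, fit_range = c(4, 6.5),
                                n_boot = 0, seed = NULL, min_depth = 1.0) {
  lt <- line_tension(pmf, fit_range)
  dg <- nucleation_free_energy(pmf, xi_nuc)
  meta <- detect_metastable(pmf, min_depth)
  se <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    bo <- bootstrap_errors(pmf, n_boot = n_boot, seed = seed,
                           xi_nuc = xi_nuc, fit_range = fit_range)
    se <- bo$std.error
  }
  structure(
    list(dG_nuc = dg, dG_nuc_se = se[1],
         gamma_pn = lt$gamma_pn, gamma_se = se[2],
         fit = lt, metastable = meta, pmf = pmf,
         xi_nuc = xi_nuc, fit_range = fit_range, n_boot = n_boot),
    class = "pore_energetics"
  )
}

#' @export
print.pore_energetics <- function(x, ...) {
  cat("Pore energetics\n")
  cat(sprintf("  dG_nuc  = %.2f kJ/mol%s  (PMF at xi = %.2f)\n", x$dG_nuc,
              if (is.finite(x$dG_nuc_se)) sprintf(" +/- %.2f", x$dG_nuc_se) else "",
              x$xi_nuc))
  cat(sprintf("  gamma   = %.2f pN%s  (fit %g <= xi <= %g, r^2 = %.4f)\n",
              x$gamma_pn,
              if (is.finite(x$gamma_se)) sprintf(" +/- %.2f", x$gamma_se) else "",
              x$fit_range[1], x$fit_range[2], x$fit$r_squared))
  if (nrow(x$metastable) > 0) {
    cat(sprintf("  metastable pore: %d minimum(-a), deepest %.1f kJ/mol at xi = %.2f\n",
                nrow(x$metastable), max(x$metastable$depth),
                x$metastable$xi_min[which.max(x$metastable$depth)]))
  } else {
    cat("  no metastable open pore\n")
  }
  invisible(x)
}

#' @export
tidy.pore_energetics <- function(x, ...) {
  tibble(
    term = c("dG_nuc", "gamma"),
    estimate = c(x$dG_nuc, x$gamma_pn),
    std.error = c(x$dG_nuc_se, x$gamma_se),
    unit = c("kJ/mol", "pN")
  )
}

#' @export
glance.pore_energetics <- function(x, ...) {
  tibble(
    r_squared = x$fit$r_squared,
    fit_lo = x$fit_range[1], fit_hi = x$fit_range[2],
    n_fit_points = x$fit$n_points,
    n_metastable = nrow(x$metastable),
    n_boot = x$n_boot
  )
}
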