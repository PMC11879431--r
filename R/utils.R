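# internal helpers

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "poremech_validation_error")
  }
  withr::with_seed(as.integer(seed), code)
}

# Wrap coordinates into [0, box)
wrap_coords <- function(x, box) {
  x - floor(x / box) * box
}

# Minimum-image displacement for an orthorhombic periodic box
min_image <- function(dx, box) {
  dx - box * round(dx / box)
}

# Robust estimate of iid point noise from second differences of a curve
# sampled on a (possibly uneven) grid; exact 0 for locally linear data.
estimate_point_noise <- function(y) {
  if (length(y) < 5) return(0)
  d2 <- diff(y, differences = 2)
  # second difference of iid noise has variance 6 sigma^2
  stats::mad(d2, center = 0) / sqrt(6)
}

# Centred running mean with window half-width `half` (shrinking at edges).
# Monotone input gives monotone output.
running_mean <- function(y, half) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(min), format(max)),
          class = "poremech_validation_error")
  }
  invisible(x)
}
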