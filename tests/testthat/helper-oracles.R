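# Independent oracles used across the suite. Each is a deliberately naive
# implementation (explicit loops, closed forms) kept separate from the
# package's computational path.

# Exhaustive MDA8 scan: for one hourly series, try every candidate start
# hour, score windows by sum-of-present / count, apply the completeness
# rules directly.
mda8_brute <- function(x, starts0 = 0:23, min_hours = 6, min_windows = 13) {
  n_days <- length(x) / 24
  out <- rep(NA_real_, n_days)
  for (d in seq_len(n_days)) {
    best <- -Inf
    n_valid <- 0L
    for (s in starts0) {
      idx <- (d - 1) * 24 + s + (1:8)   # beyond-record hours index as NA
      v <- x[idx]
      nv <- sum(!is.na(v))
      if (nv >= min_hours) {
        n_valid <- n_valid + 1L
        m <- sum(v, na.rm = TRUE) / nv
        if (m > best) best <- m
      }
    }
    if (n_valid >= min_windows) out[d] <- best
  }
  out
}

# Closed-form orthogonal-regression slope from the 2x2 covariance moments.
odr_slope_closed <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  ((syy - sxx) + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

# Scalar log-linear attributable deaths, written out longhand.
deaths_scalar <- function(p, br, rr, increment, dx) {
  p * br * (1 - exp(-(log(rr) / increment) * dx))
}

# Tiny default grid and a deterministic hourly ozone field for metric tests.
toy_grid <- function(n_lat = 3, n_lon = 4) grid_spec(n_lat, n_lon)

constant_o3_field <- function(grid, value, n_days = 2, ...) {
  concentration_field(matrix(value, n_days * 24, n_cells(grid)), grid,
                      "O3", "hourly", ...)
}

surface_of <- function(grid, values, metric = "MDA8_4th_max", units = "ppb") {
  exposure_surface(values, grid, metric = metric, units = units)
}
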