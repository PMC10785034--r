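# Regulatory-style exposure metrics and paired-scenario attribution.

#' Daily maximum 8-hour average ozone (MDA8)
#'
#' For each local day and cell, 8-hour running means are formed at every
#' candidate start hour; a window may extend into the next day. A window is
#' valid when at least `min_hours` of its 8 hourly values are present (the
#' mean is taken over the present values); the day's MDA8 is the maximum
#' over valid windows, and the day itself is missing when fewer than
#' `min_windows` windows are valid. By default all 24 start hours are used;
#' `start_hours = "7to23"` restricts candidates to the 7:00-23:00 variant.
#'
#' @param hourly An hourly ozone [concentration_field()].
#' @param start_hours `"all"` (start hours 0..23) or `"7to23"`.
#' @param min_hours Minimum present hourly values per valid window (of 8).
#' @param min_windows Minimum valid windows per valid day.
#' @return A daily `aq_field` of MDA8 values (`NA` for invalid days).
#' @export
mda8_daily <- function(hourly, start_hours = c("all", "7to23"),
                       min_hours = 6L, min_windows = 13L) {
  start_hours <- match.arg(start_hours)
  if (!inherits(hourly, "aq_field") || hourly$cadence != "hourly") {
    stop("mda8_daily requires an hourly concentration field")
  }
  if (hourly$pollutant != "O3") stop("mda8_daily is defined for ozone fields")
  x <- hourly$values
  n_hours <- nrow(x)
  if (n_hours %% 24L != 0L) stop("hourly record must cover whole days")
  n_days <- n_hours %/% 24L
  nc <- ncol(x)
  starts0 <- if (start_hours == "all") 0:23 else 7:23

  # Rolling 8-h means: windows at the end of the record extend into absent
  # hours, which count as missing. Sums accumulate the 8 hourly values in
  # chronological order (rowSums over an explicit offset array), so a window
  # mean is bit-identical to sum(values)/count on the same hours.
  xp <- rbind(x, matrix(NA_real_, 7L, nc))
  present <- !is.na(xp)
  x0 <- ifelse(present, xp, 0)
  wmean <- matrix(NA_real_, n_hours, nc)
  block <- 256L
  for (b0 in seq(1L, nc, by = block)) {
    cols <- b0:min(b0 + block - 1L, nc)
    av <- array(0, c(n_hours, length(cols), 8L))
    ac <- array(0, c(n_hours, length(cols), 8L))
    for (k in 0:7) {
      av[, , k + 1L] <- x0[(1:n_hours) + k, cols, drop = FALSE]
      ac[, , k + 1L] <- present[(1:n_hours) + k, cols, drop = FALSE]
    }
    wsum <- rowSums(av, dims = 2L)
    wcnt <- rowSums(ac, dims = 2L)
    wm <- wsum / wcnt
    wm[wcnt < min_hours] <- NA_real_
    wmean[, cols] <- wm
  }

  out <- matrix(NA_real_, n_days, nc)
  for (d in seq_len(n_days)) {
    rows <- (d - 1L) * 24L + starts0 + 1L
    wm <- wmean[rows, , drop = FALSE]
    nvalid <- colSums(!is.na(wm))
    mx <- suppressWarnings(apply(wm, 2L, max, na.rm = TRUE))
    mx[nvalid < min_windows] <- NA_real_
    mx[!is.finite(mx)] <- NA_real_
    out[d, ] <- mx
  }
  concentration_field(out, hourly$grid, "O3", "daily",
                      met_year = hourly$met_year, scenario = hourly$scenario,
                      units = hourly$units, start_month = hourly$start_month)
}

#' Annual n-th highest daily value
#'
#' Per cell, the n-th largest daily value in descending order with
#' duplicates kept (n = 4 gives the basis of the US ozone design value).
#' Cells with fewer than `n` valid days become missing with a warning.
#'
#' @param daily A daily [concentration_field()].
#' @param n Rank of the order statistic (>= 1).
#' @return An [exposure_surface()].
#' @export
annual_nth_highest <- function(daily, n = 4L) {
  if (!inherits(daily, "aq_field") || daily$cadence != "daily") {
    stop("annual_nth_highest requires a daily field")
  }
  vals <- apply(daily$values, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < n) NA_real_ else sort(v, decreasing = TRUE)[n]
  })
  if (anyNA(vals)) {
    warning(sprintf("%d cell(s) have fewer than %d valid days; set to missing",
                    sum(is.na(vals)), n))
  }
  exposure_surface(vals, daily$grid,
                   metric = if (daily$pollutant == "O3" && n == 4L)
                     "MDA8_4th_max" else sprintf("nth_highest_%d", n),
                   units = daily$units, met_year = daily$met_year,
                   scenario = daily$scenario)
}

#' Period mean of a field
#'
#' Per-cell arithmetic mean over the (optionally windowed) time axis; a cell
#' is missing when less than `min_coverage` of the window's steps are valid.
#'
#' @param field A [concentration_field()].
#' @param window Integer time indices to average over (default: all).
#' @param min_coverage Minimum valid fraction for a cell to be reported.
#' @return An [exposure_surface()].
#' @export
period_mean <- function(field, window = NULL, min_coverage = 0.75) {
  if (!inherits(field, "aq_field")) stop("period_mean requires an aq_field")
  if (is.null(window)) window <- seq_len(nrow(field$values))
  if (length(window) == 0) stop("window must be non-empty")
  if (any(window < 1 | window > nrow(field$values))) {
    stop("window indices fall outside the time axis")
  }
  x <- field$values[window, , drop = FALSE]
  cov <- colMeans(!is.na(x))
  m <- colMeans(x, na.rm = TRUE)
  m[cov < min_coverage] <- NA_real_
  m[!is.finite(m)] <- NA_real_
  exposure_surface(m, field$grid,
                   metric = paste0(field$pollutant, "_period_mean"),
                   units = field$units, met_year = field$met_year,
                   scenario = field$scenario,
                   window = sprintf("steps %d..%d", min(window), max(window)))
}

#' Population-weighted mean and spread of an exposure surface
#'
#' The population-weighted mean `sum(p*x)/sum(p)` over valid (optionally
#' masked) cells, with both the population-weighted standard deviation and
#' the unweighted cell standard deviation (both are reported because either
#' convention is found in practice).
#'
#' @param surface An [exposure_surface()].
#' @param pop An `aq_population` from [generate_population()] (or a numeric
#'   vector of weights over cells).
#' @param mask Optional logical vector over cells.
#' @return List with `mean`, `sd` (population-weighted) and `sd_unweighted`.
#' @export
population_weighted <- function(surface, pop, mask = NULL) {
  p <- if (inherits(pop, "aq_population")) pop$values else as.numeric(pop)
  if (inherits(pop, "aq_population")) check_same_grid(surface$grid, pop$grid)
  x <- surface$values
  keep <- !is.na(x)
  if (!is.null(mask)) keep <- keep & mask
  if (sum(p[keep]) <= 0) stop("total population over the mask is zero")
  p <- p[keep]; x <- x[keep]
  m <- sum(p * x) / sum(p)
  list(mean = m,
       sd = sqrt(sum(p * (x - m)^2) / sum(p)),
       sd_unweighted = if (length(x) > 1) stats::sd(x) else 0)
}

#' Attribute an exposure change to emissions versus meteorology
#'
#' Given three surfaces from the paired-run design -- meteorology A with
#' business-as-usual emissions, meteorology B with the same emissions, and
#' meteorology B with perturbed emissions -- the emission effect is the
#' difference at fixed meteorology, the meteorology effect the difference at
#' fixed emissions, and the two telescope exactly to the total change.
#'
#' @param f_ab Surface for (met A, BAU).
#' @param f_bb Surface for (met B, BAU).
#' @param f_bc Surface for (met B, perturbed scenario).
#' @return List of `aq_surface`s: `met_effect`, `emission_effect`, `total`.
#' @export
attribute_change <- function(f_ab, f_bb, f_bc) {
  check_same_grid(f_ab$grid, f_bb$grid); check_same_grid(f_bb$grid, f_bc$grid)
  tagged <- nzchar(f_ab$scenario) && nzchar(f_bb$scenario) && nzchar(f_bc$scenario)
  if (tagged) {
    if (f_ab$scenario != f_bb$scenario) {
      stop("f_ab and f_bb must share the emission scenario (the BAU pair)")
    }
    if (!identical(f_bb$met_year, f_bc$met_year)) {
      stop("f_bb and f_bc must share the meteorology year")
    }
    if (identical(f_ab$met_year, f_bb$met_year)) {
      stop("f_ab and f_bb must differ in meteorology year")
    }
  }
  list(met_effect = f_bb - f_ab,
       emission_effect = f_bc - f_bb,
       total = f_bc - f_ab)
}

#' Monitor-site change statistics
#'
#' Samples two exposure surfaces at monitor locations (nearest grid-cell
#' centre, mirroring a monitor-in-cell comparison) and summarises the
#' per-site change `y2 - y1` as a mean and standard deviation across sites.
#'
#' @param surface_y1,surface_y2 [exposure_surface()]s on one grid.
#' @param sites Data frame with `lat` and `lon` columns; sites outside the
#'   domain are an error.
#' @return List with `mean`, `sd`, `n_sites` and the per-site `delta`.
#' @export
site_change_stats <- function(surface_y1, surface_y2, sites) {
  check_same_grid(surface_y1$grid, surface_y2$grid)
  cells <- cell_of(surface_y1$grid, sites$lat, sites$lon)
  delta <- surface_y2$values[cells] - surface_y1$values[cells]
  list(mean = mean(delta, na.rm = TRUE),
       sd = if (sum(!is.na(delta)) > 1) stats::sd(delta, na.rm = TRUE) else 0,
       n_sites = length(delta), delta = delta)
}

#' Formaldehyde-to-NO2 column ratio (FNR)
#'
#' Cell-wise ratio of the period-mean HCHO column to the period-mean NO2
#' column. The ratio of period means (not the mean of instantaneous ratios)
#' is used, matching how column averages are compared; cells with missing
#' or non-positive mean NO2 become missing with a warning.
#'
#' @param hcho_col,no2_col Column [concentration_field()]s on one grid and
#'   time axis (cadence `"overpass"` or `"daily"`).
#' @param min_coverage Passed to [period_mean()].
#' @return An [exposure_surface()] of unitless ratios.
#' @export
fnr <- function(hcho_col, no2_col, min_coverage = 0.75) {
  check_same_grid(hcho_col$grid, no2_col$grid)
  h <- period_mean(hcho_col, min_coverage = min_coverage)$values
  n <- period_mean(no2_col, min_coverage = min_coverage)$values
  bad <- is.na(n) | n <= 0
  if (all(bad)) stop("no cell has a positive mean NO2 column")
  if (any(bad)) {
    warning(sprintf("%d cell(s) with zero/missing NO2 column set to missing",
                    sum(bad)))
  }
  r <- h / n
  r[bad] <- NA_real_
  exposure_surface(r, hcho_col$grid, metric = "FNR", units = "1",
                   met_year = hcho_col$met_year, scenario = hcho_col$scenario)
}

#' Classify ozone-formation regime from FNR
#'
#' Cells with FNR below `low` are VOC-limited, above `high` NOx-limited,
#' and inside the closed interval `[low, high]` in the transition regime.
#'
#' @param fnr_surface An FNR [exposure_surface()].
#' @param low,high Regime bounds with `low < high` (e.g. 4.1 and 5.0 for
#'   Los Angeles-style transition bounds).
#' @return Character vector over cells (`NA` where FNR is missing).
#' @export
classify_regime <- function(fnr_surface, low = 4.1, high = 5.0) {
  if (low >= high) stop("low must be < high")
  x <- fnr_surface$values
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x < low] <- "VOC-limited"
  out[!is.na(x) & x >= low & x <= high] <- "transition"
  out[!is.na(x) & x > high] <- "NOx-limited"
  out
}
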