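# Synthetic scenario generator.
#
# Emulates the statistical structure of a chemical-transport-model run
# without running one: hourly ozone as background + seasonal and diurnal
# sinusoids + a smooth spatial anthropogenic enhancement scaled by monthly
# activity reductions + AR(1) meteorological noise; daily PM2.5 as a
# log-normal process whose anthropogenic share carries the same monthly
# reductions. The meteorological noise stream is seeded from (seed,
# met_year) only, and the emission term is purely deterministic, so a pair
# of scenarios driven by the same meteorology differs exactly by the
# injected emission signal -- the property the paired-run attribution
# operator relies on.

# Deterministic 31-adic label hash, kept below 2^31 so derived seeds stay
# valid R integers.
hash_label <- function(...) {
  s <- paste(c(...), collapse = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 1999999973
  h
}

stream_seed <- function(seed, ...) {
  as.integer((seed %% 65011) * 33013 + hash_label(...)) %% 2147483562L
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles every knob of one synthetic model run: the meteorology-year label
#' (which selects the noise stream), the emission scenario label, the ozone
#' background and anthropogenic enhancement, diurnal/seasonal cycle
#' amplitudes, AR(1) noise parameters, the 12 monthly fractional reductions
#' applied to the anthropogenic share, and the PM2.5 log-normal parameters.
#'
#' @param met_year Meteorology-year label; fields sharing it share the same
#'   noise realisation for a given seed.
#' @param scenario `"BAU"`, `"COV"` or `"REB"`. A BAU configuration must have
#'   all monthly reductions equal to zero.
#' @param o3_background Background ozone (ppb), never scaled.
#' @param o3_enhancement Peak anthropogenic ozone enhancement (ppb); the
#'   spatial pattern is the fixed smooth surface of [enhancement_pattern()].
#' @param diurnal_amplitude,seasonal_amplitude Sinusoid amplitudes (ppb).
#' @param ar1_rho Lag-1 autocorrelation of the hourly met noise, in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of the met noise (ppb).
#' @param monthly_reduction Numeric vector of 12 fractions in `[0, 1]`
#'   (January..December) multiplying down the anthropogenic share.
#' @param pm25_median,pm25_gsd Median (ug m-3) and geometric standard
#'   deviation (> 1) of the daily PM2.5 log-normal draws.
#' @param pm25_anthro_frac Share of PM2.5 subject to the monthly reductions.
#' @param seed Base integer seed for this run.
#' @return An object of class `aq_scenario_config`.
#' @export
scenario_config <- function(met_year = "met2020",
                            scenario = c("BAU", "COV", "REB"),
                            o3_background = 30, o3_enhancement = 12,
                            diurnal_amplitude = 8, seasonal_amplitude = 10,
                            ar1_rho = 0.6, noise_sd = 5,
                            monthly_reduction = rep(0, 12),
                            pm25_median = 8, pm25_gsd = 1.6,
                            pm25_anthro_frac = 0.35, seed = 1L) {
  scenario <- match.arg(scenario)
  if (o3_background < 0 || o3_enhancement < 0 ||
      diurnal_amplitude < 0 || seasonal_amplitude < 0) {
    stop("amplitudes and background must be non-negative")
  }
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(monthly_reduction) != 12 ||
      any(monthly_reduction < 0 | monthly_reduction > 1)) {
    stop("monthly_reduction must be 12 fractions in [0, 1]")
  }
  if (scenario == "BAU" && any(monthly_reduction != 0)) {
    stop("a BAU scenario must have monthly_reduction identically zero")
  }
  if (pm25_gsd < 1) stop("pm25_gsd must be >= 1")
  if (pm25_anthro_frac < 0 || pm25_anthro_frac > 1) {
    stop("pm25_anthro_frac must lie in [0, 1]")
  }
  structure(list(met_year = met_year, scenario = scenario,
                 o3_background = o3_background, o3_enhancement = o3_enhancement,
                 diurnal_amplitude = diurnal_amplitude,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_rho = ar1_rho, noise_sd = noise_sd,
                 monthly_reduction = as.numeric(monthly_reduction),
                 pm25_median = pm25_median, pm25_gsd = pm25_gsd,
                 pm25_anthro_frac = pm25_anthro_frac,
                 seed = as.integer(seed)),
            class = "aq_scenario_config")
}

#' Fixed spatial pattern of the anthropogenic enhancement
#'
#' A deterministic smooth surface in (0, 1]: a broad urban plume plus a
#' secondary source region, identical for every scenario and meteorology so
#' that emission effects are spatially coherent across paired runs.
#'
#' @param grid An [grid_spec()] object.
#' @return Numeric vector over cells (column-major, latitude fastest).
#' @export
enhancement_pattern <- function(grid) {
  u <- (seq_len(grid$n_lat) - 0.5) / grid$n_lat
  v <- (seq_len(grid$n_lon) - 0.5) / grid$n_lon
  uu <- matrix(u, grid$n_lat, grid$n_lon)
  vv <- matrix(v, grid$n_lat, grid$n_lon, byrow = TRUE)
  p <- 0.25 +
    0.75 * exp(-((uu - 0.35)^2 + (vv - 0.30)^2) / (2 * 0.18^2)) +
    0.45 * exp(-((uu - 0.72)^2 + (vv - 0.75)^2) / (2 * 0.10^2))
  as.numeric(pmin(p, 1))
}

# Deterministic (noise-free) hourly ozone component of a scenario, exposed
# for ground-truth checks. Hour t runs 1..24*n_days in local standard time.
o3_deterministic <- function(config, grid, n_days = 365L, start_month = 4L) {
  n_hours <- 24L * n_days
  day <- rep(seq_len(n_days), each = 24L)
  hod <- rep(0:23, times = n_days)
  doy <- doy_of_day(day, start_month)
  mon <- month_of_day(day, start_month)
  seasonal <- config$seasonal_amplitude * cos(2 * pi * (doy - 201) / 365)
  diurnal <- config$diurnal_amplitude * sin(2 * pi * (hod - 9) / 24)
  temporal <- config$o3_background + seasonal + diurnal
  enh <- config$o3_enhancement * enhancement_pattern(grid)
  scale_t <- 1 - config$monthly_reduction[mon]
  # outer structure: [n_hours, n_cells]
  matrix(temporal, n_hours, length(enh)) +
    outer(scale_t, enh)
}

ar1_noise <- function(n_time, n_cell, rho, sd, seed) {
  if (sd == 0) return(matrix(0, n_time, n_cell))
  withr::with_seed(seed, {
    innov_sd <- sd * sqrt(1 - rho^2)
    x0 <- stats::rnorm(n_cell, 0, sd)
    eps <- matrix(stats::rnorm(n_time * n_cell, 0, innov_sd), n_time, n_cell)
    out <- matrix(0, n_time, n_cell)
    prev <- x0
    for (t in seq_len(n_time)) {
      prev <- rho * prev + eps[t, ]
      out[t, ] <- prev
    }
    out
  })
}

#' Generate paired scenario concentration fields
#'
#' Produces, for each configuration, an hourly ozone field and a daily PM2.5
#' field on the shared grid. The met-noise stream depends only on
#' `(seed, met_year)` and the emission term is deterministic, so two
#' configurations sharing `met_year` and `seed` differ exactly by
#' `enhancement x monthly_reduction` cell-wise (ozone) and by the reduced
#' anthropogenic share (PM2.5).
#'
#' @param grid An [grid_spec()] object.
#' @param configs List of [scenario_config()] objects. A non-BAU
#'   configuration requires a BAU partner with the same `met_year`.
#' @param n_days Length of the simulated record in days (365-day calendar).
#' @param start_month Calendar month of day 1.
#' @return Named list (one element per `met_year.scenario`) of lists with
#'   components `o3` and `pm25` ([concentration_field()] objects) and
#'   `config`.
#' @export
generate_scenario_fields <- function(grid, configs, n_days = 365L,
                                     start_month = 4L) {
  if (inherits(configs, "aq_scenario_config")) configs <- list(configs)
  tags <- vapply(configs, function(cf) paste(cf$met_year, cf$scenario, sep = "."),
                 character(1))
  if (anyDuplicated(tags)) stop("duplicate (met_year, scenario) configurations")
  for (cf in configs) {
    if (cf$scenario != "BAU" &&
        !any(vapply(configs, function(o)
          o$scenario == "BAU" && o$met_year == cf$met_year, logical(1)))) {
      stop(sprintf("scenario %s (met %s) has no BAU partner with the same met_year",
                   cf$scenario, cf$met_year))
    }
  }
  out <- vector("list", length(configs))
  names(out) <- tags
  n_hours <- 24L * n_days
  day_of_hour <- rep(seq_len(n_days), each = 24L)
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    det <- o3_deterministic(cf, grid, n_days, start_month)
    noise <- ar1_noise(n_hours, n_cells(grid), cf$ar1_rho, cf$noise_sd,
                       stream_seed(cf$seed, cf$met_year, "o3"))
    o3 <- concentration_field(pmax(det + noise, 0), grid, "O3", "hourly",
                              met_year = cf$met_year, scenario = cf$scenario,
                              start_month = start_month)
    mon_d <- month_of_day(seq_len(n_days), start_month)
    draws <- withr::with_seed(stream_seed(cf$seed, cf$met_year, "pm25"), {
      matrix(stats::rlnorm(n_days * n_cells(grid),
                           meanlog = log(cf$pm25_median),
                           sdlog = log(cf$pm25_gsd)),
             n_days, n_cells(grid))
    })
    share <- (1 - cf$pm25_anthro_frac) +
      cf$pm25_anthro_frac * (1 - cf$monthly_reduction[mon_d])
    pm <- concentration_field(draws * share, grid, "PM25", "daily",
                              met_year = cf$met_year, scenario = cf$scenario,
                              start_month = start_month)
    out[[k]] <- list(o3 = o3, pm25 = pm, config = cf)
  }
  out
}

#' Generate a clustered log-normal population grid
#'
#' Population mass decays with squared distance from randomly placed urban
#' centres and carries multiplicative log-normal dispersion; the grid is then
#' normalised to a configured national total. With `decay = 0` and
#' `dispersion = 0` the surface is uniform.
#'
#' @param grid An [grid_spec()] object.
#' @param n_centers Number of urban centres (>= 1).
#' @param total National population total the grid is normalised to.
#' @param decay Squared-distance decay rate in units of the normalised
#'   domain (0 disables decay).
#' @param dispersion Log-scale standard deviation of cell-level dispersion.
#' @param seed Integer seed.
#' @return List with `values` (persons per cell) and the `grid`, class
#'   `aq_population`.
#' @export
generate_population <- function(grid, n_centers = 8, total = 3.3e8,
                                decay = 25, dispersion = 0.5, seed = 1L) {
  if (n_centers < 1) stop("n_centers must be >= 1")
  if (decay < 0 || dispersion < 0) stop("decay and dispersion must be >= 0")
  u <- (rep(seq_len(grid$n_lat), grid$n_lon) - 0.5) / grid$n_lat
  v <- (rep(seq_len(grid$n_lon), each = grid$n_lat) - 0.5) / grid$n_lon
  vals <- withr::with_seed(stream_seed(seed, "population"), {
    cu <- stats::runif(n_centers)
    cv <- stats::runif(n_centers)
    w <- stats::runif(n_centers, 0.5, 1.5)
    base <- rowSums(vapply(seq_len(n_centers), function(c)
      w[c] * exp(-decay * ((u - cu[c])^2 + (v - cv[c])^2)), numeric(length(u))))
    base * exp(stats::rnorm(length(u), 0, dispersion))
  })
  vals <- vals * (total / sum(vals))
  structure(list(values = vals, grid = grid), class = "aq_population")
}

#' Generate county-blocked baseline mortality rates
#'
#' Tiles the grid with axis-aligned rectangular county blocks; each county
#' draws one all-cause baseline mortality rate from a normal distribution
#' truncated to (0, 1), constant across the county's cells.
#'
#' @param grid An [grid_spec()] object.
#' @param n_counties Number of county blocks (tiled as close to square as the
#'   factorisation allows).
#' @param mean_rate Mean annual mortality rate (deaths / person / yr), in (0, 1).
#' @param sd_rate Between-county standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `values` (rate per cell), `county_id` (integer per
#'   cell) and the `grid`, class `aq_mortality`.
#' @export
generate_mortality <- function(grid, n_counties = 12, mean_rate = 0.009,
                               sd_rate = 0.002, seed = 1L) {
  if (mean_rate <= 0 || mean_rate >= 1) stop("mean_rate must lie in (0, 1)")
  if (sd_rate < 0) stop("sd_rate must be >= 0")
  kr <- floor(sqrt(n_counties))
  while (kr > 1 && n_counties %% kr != 0) kr <- kr - 1
  kc <- n_counties / kr
  row_block <- pmin(ceiling(seq_len(grid$n_lat) / (grid$n_lat / kr)), kr)
  col_block <- pmin(ceiling(seq_len(grid$n_lon) / (grid$n_lon / kc)), kc)
  county <- as.integer(outer(row_block, (col_block - 1) * kr, "+"))
  rates <- withr::with_seed(stream_seed(seed, "mortality"), {
    r <- stats::rnorm(n_counties, mean_rate, sd_rate)
    while (any(bad <- r <= 0 | r >= 1)) {
      r[bad] <- stats::rnorm(sum(bad), mean_rate, sd_rate)
    }
    r
  })
  structure(list(values = rates[county], county_id = county, grid = grid),
            class = "aq_mortality")
}

#' Generate monthly activity-scaling series
#'
#' Builds, per sector, a 12-month series of emission scalings relative to the
#' baseline year. The business-as-usual series is identically 1; the
#' perturbed series dips to `1 - depth` at the trough month and relaxes
#' exponentially back toward 1 at the sector's rebound rate, with a
#' half-depth shoulder the month before the trough (lockdowns ramped in
#' during March for an April trough).
#'
#' @param profiles Named list, one element per sector, each a list with
#'   `depth` (fraction in `[0, 1]`), `trough` (calendar month 1-12) and
#'   `rebound` (per-month exponential recovery rate, >= 0).
#' @param months Integer months covered (default January..December).
#' @return Data frame with columns `sector`, `month`, `scaling`, class
#'   `aq_activity`.
#' @examples
#' act <- generate_activity(list(onroad_gasoline =
#'   list(depth = 0.4, trough = 4, rebound = 0.3)))
#' subset(act, month == 4)   # April scaling 0.6
#' @export
generate_activity <- function(profiles, months = 1:12) {
  rows <- lapply(names(profiles), function(sec) {
    p <- profiles[[sec]]
    if (p$depth < 0 || p$depth > 1) stop("depth must lie in [0, 1]")
    if (p$rebound < 0) stop("rebound rate must be >= 0")
    s <- rep(1, length(months))
    after <- months >= p$trough
    s[after] <- 1 - p$depth * exp(-p$rebound * (months[after] - p$trough))
    s[months == p$trough - 1] <- 1 - p$depth / 2
    data.frame(sector = sec, month = months, scaling = s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aq_activity", "data.frame")
  out
}

#' Generate a satellite-style retrieval scene
#'
#' Samples pixels over the grid and builds, for each, a layered a priori
#' profile, a scattering-weight profile increasing with altitude, an original
#' air-mass factor self-consistent with the two, a reported vertical column
#' equal to the true model column times `(1 + noise x N(0,1))`, and quality
#' fields (qa value, cloud fraction, solar zenith angle). With `noise = 0`
#' and `apriori_deviation = 0` the pixel columns and profiles reproduce the
#' model exactly.
#'
#' @param model_col An [exposure_surface()] of true model columns
#'   (molec cm-2), or a numeric vector over cells.
#' @param grid An [grid_spec()] object.
#' @param n_pixels Number of pixels (>= 1).
#' @param noise Relative (fractional) standard deviation of column noise.
#' @param apriori_deviation Maximum fractional perturbation of the a priori
#'   profile shape relative to the model shape (0 means identical shapes).
#' @param n_layers Number of vertical layers (layer 1 at the surface); all
#'   layers are tropospheric (`tropopause_layer = n_layers`).
#' @param seed Integer seed.
#' @return A list of class `aq_scene`: `pixels` data frame (lat, lon, cell,
#'   vcd, amf_orig, qa, cloud_fraction, sza, tropopause_layer) plus matrices
#'   `scattering_weights`, `apriori`, `model_profile` of size
#'   `[n_pixels, n_layers]`.
#' @export
generate_satellite_scene <- function(model_col, grid, n_pixels = 500,
                                     noise = 0.1, apriori_deviation = 0.3,
                                     n_layers = 12L, seed = 1L) {
  if (n_pixels < 1) stop("n_pixels must be >= 1")
  cols <- if (inherits(model_col, "aq_surface")) model_col$values else as.numeric(model_col)
  if (length(cols) != n_cells(grid)) stop("model_col must cover every grid cell")
  lay <- seq_len(n_layers)
  withr::with_seed(stream_seed(seed, "satellite"), {
    cell <- sample.int(n_cells(grid), n_pixels, replace = TRUE)
    i <- ((cell - 1L) %% grid$n_lat) + 1L
    j <- ((cell - 1L) %/% grid$n_lat) + 1L
    lat <- grid$lat0 + (i - 1) * grid$dlat +
      stats::runif(n_pixels, -0.4, 0.4) * grid$dlat
    lon <- grid$lon0 + (j - 1) * grid$dlon +
      stats::runif(n_pixels, -0.4, 0.4) * grid$dlon
    true_col <- cols[cell]
    # model shape: exponential decay from the surface over ~3 layers
    shp_m <- exp(-(lay - 1) / 3)
    shp_m <- shp_m / sum(shp_m)
    model_profile <- outer(true_col, shp_m)
    delta <- stats::runif(n_pixels, -apriori_deviation, apriori_deviation)
    apriori <- t(vapply(delta, function(d) {
      s <- exp(-(lay - 1) / (3 * (1 + d)))
      s / sum(s)
    }, numeric(n_layers))) * true_col
    sw_shape <- 0.3 + 0.7 * (lay - 1) / (n_layers - 1)
    sw <- outer(stats::runif(n_pixels, 0.8, 1.2), sw_shape)
    amf_orig <- rowSums(sw * apriori) / rowSums(apriori)
    vcd <- true_col * (1 + noise * stats::rnorm(n_pixels))
    px <- data.frame(lat = lat, lon = lon, cell = cell, vcd = vcd,
                     amf_orig = amf_orig,
                     qa = stats::runif(n_pixels)^0.25,
                     cloud_fraction = stats::rbeta(n_pixels, 1.2, 5),
                     sza = stats::runif(n_pixels, 20, 75),
                     tropopause_layer = n_layers)
    structure(list(pixels = px, scattering_weights = sw, apriori = apriori,
                   model_profile = model_profile, grid = grid,
                   n_layers = as.integer(n_layers)),
              class = "aq_scene")
  })
}
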