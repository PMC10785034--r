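#' Gridded time-resolved concentration field
#'
#' The basic container for modelled pollutant values: a `n_time x n_cell`
#' matrix on a shared [grid_spec()] grid, tagged with the pollutant, the
#' meteorology year driving the simulation and the emission scenario. Hourly
#' cadence is used for ozone (so MDA8 windows are well defined), daily for
#' PM2.5, and "overpass" for satellite-style column fields.
#'
#' @param values Numeric matrix `[n_time, n_cells(grid)]`; `NA` marks missing.
#' @param grid An [grid_spec()] object.
#' @param pollutant One of `"O3"`, `"PM25"`, `"NO2_col"`, `"HCHO_col"`.
#' @param cadence One of `"hourly"`, `"daily"`, `"overpass"`.
#' @param met_year Label of the meteorological year driving the field.
#' @param scenario Emission scenario label (e.g. `"BAU"`, `"COV"`, `"REB"`).
#' @param units Units string (`"ppb"`, `"ug m-3"`, `"molec cm-2"`).
#' @param start_month Calendar month of time step 1 (see [month_of_day()]).
#' @return An object of class `aq_field`.
#' @export
concentration_field <- function(values, grid,
                                pollutant = c("O3", "PM25", "NO2_col", "HCHO_col"),
                                cadence = c("hourly", "daily", "overpass"),
                                met_year = "met", scenario = "BAU",
                                units = NULL, start_month = 4L) {
  pollutant <- match.arg(pollutant)
  cadence <- match.arg(cadence)
  values <- as.matrix(values)
  if (ncol(values) != n_cells(grid)) {
    stop("values must have one column per grid cell")
  }
  if (any(values < 0, na.rm = TRUE)) stop("concentrations must be >= 0 or missing")
  if (is.null(units)) {
    units <- switch(pollutant, O3 = "ppb", PM25 = "ug m-3", "molec cm-2")
  }
  structure(list(values = values, grid = grid, pollutant = pollutant,
                 cadence = cadence, met_year = met_year, scenario = scenario,
                 units = units, start_month = as.integer(start_month)),
            class = "aq_field")
}

#' @export
print.aq_field <- function(x, ...) {
  cat(sprintf("<aq_field> %s [%s], %d %s steps on %dx%d grid, met=%s scen=%s\n",
              x$pollutant, x$units, nrow(x$values), x$cadence,
              x$grid$n_lat, x$grid$n_lon, x$met_year, x$scenario))
  invisible(x)
}

#' One-number-per-cell exposure surface
#'
#' Holds an aggregated exposure metric (4th-highest MDA8, period mean, an
#' FNR ratio, a column average, ...) as a vector with one value per grid
#' cell, tagged with the metric name and averaging window.
#'
#' @param values Numeric vector of length `n_cells(grid)`; `NA` marks cells
#'   where the metric could not be computed.
#' @param grid An [grid_spec()] object.
#' @param metric Metric label, e.g. `"MDA8_4th_max"`, `"PM25_annual_mean"`.
#' @param units Units string.
#' @param window Free-text description of the aggregation window.
#' @param met_year,scenario Tags inherited from the source field.
#' @return An object of class `aq_surface`.
#' @export
exposure_surface <- function(values, grid, metric, units = "",
                             window = "", met_year = "", scenario = "") {
  values <- as.numeric(values)
  if (length(values) != n_cells(grid)) {
    stop("values must have one entry per grid cell")
  }
  structure(list(values = values, grid = grid, metric = metric, units = units,
                 window = window, met_year = met_year, scenario = scenario),
            class = "aq_surface")
}

#' @export
print.aq_surface <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("<aq_surface> %s [%s] on %dx%d grid (%d valid cells), window: %s\n",
              x$metric, x$units, x$grid$n_lat, x$grid$n_lon, sum(ok),
              if (nzchar(x$window)) x$window else "full record"))
  if (any(ok)) {
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(x$values[ok]), max(x$values[ok]), mean(x$values[ok])))
  }
  invisible(x)
}

#' Cell-wise arithmetic on exposure surfaces
#'
#' Differences of surfaces (scenario minus reference) keep the grid and units
#' and compose the attribution operators; see [attribute_change()].
#'
#' @param e1,e2 `aq_surface` objects on the same grid.
#' @export
#' @method - aq_surface
"-.aq_surface" <- function(e1, e2) {
  check_same_grid(e1$grid, e2$grid, "surface difference")
  exposure_surface(e1$values - e2$values, e1$grid,
                   metric = paste0("delta_", e1$metric), units = e1$units,
                   window = e1$window)
}
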