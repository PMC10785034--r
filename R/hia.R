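# Log-linear concentration-response health impact assessment.
#
# Attributable deaths per cell follow Deaths = P * BR * (1 - exp(-beta*DX)),
# with P the population, BR the baseline annual all-cause mortality rate,
# DX the exposure above the theoretical minimum-risk level (TMREL), and
# beta = ln(RR)/increment the log-linear slope of the concentration-response
# function for a relative risk RR quoted per a stated exposure increment.
# Confidence intervals propagate by recomputing the whole chain at the RR
# interval endpoints.

#' Relative risk specification
#'
#' @param rr Central relative risk (e.g. 1.02 for ozone all-cause mortality
#'   per 10 ppb; 1.06 for PM2.5 per 10 ug m-3).
#' @param ci_low,ci_high 95% interval endpoints, `1 <= ci_low <= rr <= ci_high`.
#' @param increment Exposure increment the RR is quoted per (> 0), in the
#'   pollutant's units.
#' @param tmrel Theoretical minimum-risk exposure level (same units, >= 0);
#'   26.7 ppb for ozone and 2.8 ug m-3 for PM2.5 in the default tables.
#' @param pollutant `"O3"` or `"PM25"`.
#' @param units Units string; defaults from the pollutant.
#' @return An object of class `aq_rr`.
#' @export
relative_risk <- function(rr, ci_low, ci_high, increment, tmrel,
                          pollutant = c("O3", "PM25"), units = NULL) {
  pollutant <- match.arg(pollutant)
  if (!(1 <= ci_low && ci_low <= rr && rr <= ci_high)) {
    stop("requires 1 <= ci_low <= rr <= ci_high")
  }
  if (increment <= 0) stop("increment must be > 0")
  if (tmrel < 0) stop("tmrel must be >= 0")
  if (is.null(units)) units <- if (pollutant == "O3") "ppb" else "ug m-3"
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 increment = increment, tmrel = tmrel,
                 pollutant = pollutant, units = units),
            class = "aq_rr")
}

#' Default relative-risk table
#'
#' All-cause mortality risks for long-term exposure: 1.02 (95% CI 1.01-1.04)
#' per 10 ppb ozone with a 26.7 ppb TMREL, and 1.06 (95% CI 1.04-1.08) per
#' 10 ug m-3 PM2.5 with a 2.8 ug m-3 TMREL (Turner et al.-style cohort
#' estimates).
#'
#' @return Named list of [relative_risk()] objects (`O3`, `PM25`).
#' @export
default_rr_table <- function() {
  list(O3 = relative_risk(1.02, 1.01, 1.04, increment = 10, tmrel = 26.7,
                          pollutant = "O3"),
       PM25 = relative_risk(1.06, 1.04, 1.08, increment = 10, tmrel = 2.8,
                            pollutant = "PM25"))
}

#' Log-linear slope from a relative risk
#'
#' `beta = ln(RR) / increment`, so the attributable fraction at an exposure
#' excess of exactly one increment is `1 - 1/RR`.
#'
#' @param rr An [relative_risk()] object.
#' @param which Which endpoint to use: the central RR or a CI endpoint.
#' @return Numeric slope per exposure unit.
#' @export
beta_from_rr <- function(rr, which = c("central", "low", "high")) {
  which <- match.arg(which)
  r <- switch(which, central = rr$rr, low = rr$ci_low, high = rr$ci_high)
  if (r <= 0) stop("relative risk must be positive")
  log(r) / rr$increment
}

#' Exposure above the minimum-risk level
#'
#' `DX = max(0, X - tmrel)` cell-wise, applied to the aggregated annual
#' metric (clamping after aggregation, not per day).
#'
#' @param metric An [exposure_surface()] in the RR's units.
#' @param rr An [relative_risk()] object.
#' @return An [exposure_surface()] of exposure excesses.
#' @export
excess_exposure <- function(metric, rr) {
  if (nzchar(metric$units) && metric$units != rr$units) {
    stop(sprintf("unit mismatch: metric in %s, relative risk per %s",
                 metric$units, rr$units))
  }
  exposure_surface(pmax(metric$values - rr$tmrel, 0), metric$grid,
                   metric = paste0(metric$metric, "_excess"),
                   units = metric$units, window = metric$window,
                   met_year = metric$met_year, scenario = metric$scenario)
}

#' Cell-wise attributable deaths
#'
#' `Deaths = P * BR * (1 - exp(-beta * DX))` per cell, plus the rate per
#' 100,000 people (0 where the cell is unpopulated).
#'
#' @param pop An `aq_population`.
#' @param mort An `aq_mortality`.
#' @param beta Slope per exposure unit (from [beta_from_rr()]).
#' @param dx An [exposure_surface()] of exposure excesses (>= 0; missing
#'   cells contribute no deaths).
#' @return Object of class `aq_deaths` with `deaths` and `rate_per_1e5`
#'   vectors over cells and the `grid`.
#' @export
attributable_deaths <- function(pop, mort, beta, dx) {
  check_same_grid(pop$grid, mort$grid); check_same_grid(pop$grid, dx$grid)
  if (any(dx$values < 0, na.rm = TRUE)) stop("exposure excess must be >= 0")
  x <- dx$values
  x[is.na(x)] <- 0
  deaths <- pop$values * mort$values * (1 - exp(-beta * x))
  rate <- ifelse(pop$values > 0, deaths / pop$values * 1e5, 0)
  structure(list(deaths = deaths, rate_per_1e5 = rate, grid = pop$grid,
                 beta = beta, pollutant = dx$metric),
            class = "aq_deaths")
}

#' Run the full assessment chain for one pollutant
#'
#' Computes exposure excess from the annual metric and the attributable
#' deaths surface at the central RR and at both CI endpoints (the CI is
#' propagated by endpoint substitution through the whole chain).
#'
#' @param pop An `aq_population`.
#' @param mort An `aq_mortality`.
#' @param rr An [relative_risk()].
#' @param metric An [exposure_surface()] (annual mean MDA8 for ozone,
#'   annual mean 24-h PM2.5).
#' @return List of class `aq_hia`: `central`, `low`, `high` (`aq_deaths`)
#'   and `dx`.
#' @export
hia_run <- function(pop, mort, rr, metric) {
  dx <- excess_exposure(metric, rr)
  out <- list(central = attributable_deaths(pop, mort, beta_from_rr(rr), dx),
              low = attributable_deaths(pop, mort, beta_from_rr(rr, "low"), dx),
              high = attributable_deaths(pop, mort, beta_from_rr(rr, "high"), dx),
              dx = dx, rr = rr)
  class(out) <- "aq_hia"
  out
}

#' National (or masked-region) totals with confidence interval
#'
#' @param hia An `aq_hia` from [hia_run()] (or a single `aq_deaths`, in
#'   which case no CI is available).
#' @param mask Optional logical vector over cells.
#' @return Named numeric vector `c(total, ci_low, ci_high)` (`NA` endpoints
#'   for a bare `aq_deaths`).
#' @export
summarize_deaths <- function(hia, mask = NULL) {
  tot <- function(d) {
    v <- d$deaths
    if (!is.null(mask)) {
      if (!any(mask)) stop("empty region mask")
      v <- v[mask]
    }
    sum(v)
  }
  if (inherits(hia, "aq_deaths")) {
    return(c(total = tot(hia), ci_low = NA_real_, ci_high = NA_real_))
  }
  c(total = tot(hia$central), ci_low = tot(hia$low), ci_high = tot(hia$high))
}

#' Averted deaths between two scenarios
#'
#' Cell-wise difference (reference minus perturbed), its total, and the
#' total as a percentage of the reference burden rounded to the nearest
#' integer percent (the convention used for headline "X% of attributable
#' deaths averted" figures).
#'
#' @param deaths_bau,deaths_cov `aq_deaths` surfaces (or `aq_hia` objects,
#'   in which case central estimates are differenced and the CI endpoints
#'   are differenced endpoint-wise).
#' @return List with `surface` (numeric per cell), `total`,
#'   `percent_of_bau`, and (for `aq_hia` inputs) `total_ci`.
#' @export
averted <- function(deaths_bau, deaths_cov) {
  pick <- function(x) if (inherits(x, "aq_hia")) x$central else x
  b <- pick(deaths_bau); c_ <- pick(deaths_cov)
  check_same_grid(b$grid, c_$grid)
  surf <- b$deaths - c_$deaths
  total_b <- sum(b$deaths)
  out <- list(surface = surf, total = sum(surf),
              percent_of_bau = averted_percent(total_b, sum(surf)))
  if (inherits(deaths_bau, "aq_hia") && inherits(deaths_cov, "aq_hia")) {
    out$total_ci <- c(low = sum(deaths_bau$low$deaths) - sum(deaths_cov$low$deaths),
                      high = sum(deaths_bau$high$deaths) - sum(deaths_cov$high$deaths))
  }
  out
}

#' Averted deaths as integer percent of the reference burden
#'
#' `round(100 * averted / reference)`; the scalar arithmetic behind headline
#' percentages, usable directly on reported national totals.
#'
#' @param total_bau Reference (business-as-usual) total deaths (> 0).
#' @param total_averted Averted deaths.
#' @return Integer percent.
#' @examples
#' averted_percent(74400, 4010)    # 5
#' averted_percent(124400, 4829)   # 4
#' @export
averted_percent <- function(total_bau, total_averted) {
  if (total_bau <= 0) stop("reference total must be > 0")
  as.integer(round(100 * total_averted / total_bau))
}
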