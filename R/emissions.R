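# Sectoral emission inventories and activity-based monthly scaling.
#
# An inventory is a long table of monthly emitted mass by species, sector
# and state. Near-real-time adjustment multiplies each sector's mass by its
# monthly activity scaling; fractional-change accounting then reports
# mass-weighted aggregate changes relative to a reference inventory at
# national, sectoral and state level.

CORE_SPECIES <- c("CO", "NOx", "VOC", "SO2", "NH3", "PM2.5")

#' Sectoral emission inventory
#'
#' @param entries Data frame with columns `species`, `sector`, `state`,
#'   `month` (1-12) and `value` (t / month, >= 0).
#' @param base_year Label of the inventory's base year.
#' @return The validated data frame, class `aq_inventory`, with `base_year`
#'   attribute. Species outside the six core species (CO, NOx, VOC, SO2,
#'   NH3, PM2.5) pass through with a warning.
#' @export
emission_inventory <- function(entries, base_year = "2019") {
  need <- c("species", "sector", "state", "month", "value")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns species, sector, state, month, value")
  }
  if (any(entries$value < 0)) stop("emission masses must be >= 0")
  if (any(entries$month < 1 | entries$month > 12)) stop("month must be in 1..12")
  extra <- setdiff(unique(entries$species), CORE_SPECIES)
  if (length(extra)) {
    warning(sprintf("species outside the core set pass through unvalidated: %s",
                    paste(extra, collapse = ", ")))
  }
  out <- entries[need]
  attr(out, "base_year") <- base_year
  class(out) <- c("aq_inventory", "data.frame")
  out
}

#' Apply monthly activity scalings to an inventory
#'
#' Multiplies each entry's mass by its sector's scaling for that month.
#' Every sector must either have a scaling series or be declared unscaled
#' (agricultural ammonia and fugitive dust are unscaled by default, since no
#' activity data constrain them); anything else is an error.
#'
#' @param base An [emission_inventory()].
#' @param series An [generate_activity()] data frame (`sector`, `month`,
#'   `scaling`) or anything coercible to one.
#' @param unscaled Character vector of sectors deliberately left unscaled.
#' @return A scaled `aq_inventory` on the same keys.
#' @export
apply_monthly_scaling <- function(base, series,
                                  unscaled = c("agricultural_nh3", "fugitive_dust")) {
  series <- as.data.frame(series)
  if (any(series$scaling < 0)) stop("scalings must be >= 0")
  sectors <- unique(base$sector)
  covered <- sectors %in% series$sector | sectors %in% unscaled
  if (!all(covered)) {
    stop(sprintf("sector(s) with neither a scaling series nor an unscaled declaration: %s",
                 paste(sectors[!covered], collapse = ", ")))
  }
  key_s <- paste(series$sector, series$month)
  fac <- series$scaling[match(paste(base$sector, base$month), key_s)]
  fac[base$sector %in% unscaled] <- 1
  if (anyNA(fac)) {
    stop("scaling series does not cover every month present in the inventory")
  }
  out <- base
  out$value <- base$value * fac
  out
}

group_sum <- function(inv, by) {
  stats::aggregate(inv["value"], inv[by], sum)
}

#' Fractional emission changes relative to a reference inventory
#'
#' For each reporting group the fraction is the mass-weighted aggregate
#' `sum(scaled) / sum(reference) - 1`, not an average of entry-level
#' fractions. Groups are species x month (national), species x sector x
#' month, and species x state x month; scaled and reference group masses are
#' kept alongside the fraction so period aggregates stay mass-weighted.
#'
#' @param scaled,reference [emission_inventory()] objects on matching keys.
#' @return List of class `aq_change` with data frames `national`, `sector`,
#'   `state`, each carrying `scaled`, `reference` and `fraction` columns.
#' @export
fractional_change <- function(scaled, reference) {
  mk <- function(by) {
    s <- group_sum(scaled, by)
    r <- group_sum(reference, by)
    m <- merge(r, s, by = by, all = TRUE, suffixes = c(".ref", ".scl"),
               sort = TRUE)
    if (anyNA(m$value.ref) || anyNA(m$value.scl)) {
      stop("scaled and reference inventories do not share the same keys")
    }
    if (any(m$value.ref <= 0)) {
      stop("zero reference total for a requested group")
    }
    out <- m[by]
    out$scaled <- m$value.scl
    out$reference <- m$value.ref
    out$fraction <- m$value.scl / m$value.ref - 1
    out
  }
  structure(list(national = mk(c("species", "month")),
                 sector = mk(c("species", "sector", "month")),
                 state = mk(c("species", "state", "month"))),
            class = "aq_change")
}

#' State-level percentile band of fractional changes
#'
#' Returns the `lo` and `hi` percentiles of the state-level fraction
#' distribution for one species and month (linear interpolation between
#' closest order statistics, i.e. `quantile(type = 7)`), together with the
#' national mass-weighted fraction. A dominant high-emitting state can pull
#' the national value outside the band.
#'
#' @param change An `aq_change` from [fractional_change()].
#' @param species,month Group selectors.
#' @param lo,hi Percentiles in `[0, 100]`.
#' @return Named numeric vector `c(lo_pct, hi_pct, national)`.
#' @export
state_percentile_band <- function(change, species, month, lo = 20, hi = 80) {
  st <- change$state[change$state$species == species &
                       change$state$month == month, ]
  if (nrow(st) < 2) stop("at least 2 states are required for a percentile band")
  q <- stats::quantile(st$fraction, c(lo, hi) / 100, type = 7, names = FALSE)
  nat <- change$national[change$national$species == species &
                           change$national$month == month, "fraction"]
  c(lo_pct = q[1], hi_pct = q[2], national = nat)
}

#' Period-mean fractional change with state variability
#'
#' Aggregates a species' fractional change over a set of months. The central
#' value is mass-weighted: pooled scaled mass over pooled reference mass,
#' minus one. The spread is one standard deviation of the state-level pooled
#' period fractions, with states weighted equally by default (`sd = 0` for a
#' single state, by convention).
#'
#' @param change An `aq_change` from [fractional_change()].
#' @param species Species selector.
#' @param months Non-empty integer vector of months.
#' @param weight_states_by_mass If `TRUE`, the state spread is a
#'   reference-mass-weighted standard deviation instead of equal-weight.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
period_mean_change <- function(change, species, months,
                               weight_states_by_mass = FALSE) {
  if (length(months) == 0) stop("months must be non-empty")
  nat <- change$national[change$national$species == species &
                           change$national$month %in% months, ]
  if (nrow(nat) == 0) stop("no entries for the requested species/months")
  centre <- sum(nat$scaled) / sum(nat$reference) - 1
  st <- change$state[change$state$species == species &
                       change$state$month %in% months, ]
  ssc <- tapply(st$scaled, st$state, sum)
  srf <- tapply(st$reference, st$state, sum)
  sf <- as.numeric(ssc / srf - 1)
  if (length(sf) < 2) {
    spread <- 0
  } else if (weight_states_by_mass) {
    w <- as.numeric(srf) / sum(srf)
    mu <- sum(w * sf)
    spread <- sqrt(sum(w * (sf - mu)^2))
  } else {
    spread <- stats::sd(sf)
  }
  c(mean = centre, sd = spread)
}
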