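toy_inventory <- function() {
  g <- expand.grid(species = c("NOx", "VOC"),
                   sector = c("onroad_gasoline", "point", "agricultural_nh3"),
                   state = c("CA", "TX"), month = c(4, 5),
                   stringsAsFactors = FALSE)
  g$value <- seq(10, by = 10, length.out = nrow(g))
  emission_inventory(g, base_year = "2019")
}

test_that("monthly scaling multiplies sector masses and passes unscaled sectors through", {
  base <- toy_inventory()
  series <- rbind(data.frame(sector = "onroad_gasoline", month = c(4, 5),
                             scaling = c(0.6, 0.8)),
                  data.frame(sector = "point", month = c(4, 5),
                             scaling = c(0.9, 1.0)))
  scaled <- apply_monthly_scaling(base, series)
  # brute-force oracle: walk every row and multiply by the matching factor
  for (i in seq_len(nrow(base))) {
    fac <- 1
    hit <- series$sector == base$sector[i] & series$month == base$month[i]
    if (any(hit)) fac <- series$scaling[hit]
    expect_identical(scaled$value[i], base$value[i] * fac)
  }
  # identity series leave the inventory untouched
  ident <- data.frame(sector = c("onroad_gasoline", "point"),
                      month = rep(c(4, 5), each = 2),
                      scaling = 1)
  expect_identical(apply_monthly_scaling(base, ident)$value, base$value)
  # uncovered sector is an error
  expect_error(apply_monthly_scaling(base, series[series$sector == "point", ]),
               "neither a scaling series nor an unscaled")
})

test_that("definitional April scaling example holds", {
  base <- emission_inventory(data.frame(
    species = "NOx", sector = "onroad_gasoline", state = "US",
    month = 4, value = 100))
  series <- data.frame(sector = "onroad_gasoline", month = 4, scaling = 0.6)
  expect_equal(apply_monthly_scaling(base, series)$value, 60)
})

test_that("fractional changes are mass-weighted aggregates", {
  base <- emission_inventory(data.frame(
    species = "NOx", sector = "onroad_gasoline", state = c("CA", "TX"),
    month = 4, value = c(100, 300)))
  scaled <- base; scaled$value <- c(80, 300)
  ch <- fractional_change(scaled, base)
  expect_equal(ch$national$fraction, -0.05)
  st <- ch$state[order(ch$state$state), ]
  expect_equal(st$fraction, c(-0.20, 0.00))
  # scaled == reference gives identically zero fractions
  ch0 <- fractional_change(base, base)
  expect_true(all(ch0$national$fraction == 0))
  # halving a single sector gives -0.5 for its sector group
  half <- base; half$value <- base$value / 2
  expect_equal(fractional_change(half, base)$sector$fraction, -0.5)
})

test_that("mass conservation holds across groupings before and after scaling", {
  base <- demo_inventory()
  act <- generate_activity(list(
    onroad_gasoline = list(depth = 0.4, trough = 4, rebound = 0.3),
    onroad_diesel = list(depth = 0.2, trough = 4, rebound = 0.25),
    nonroad = list(depth = 0.25, trough = 4, rebound = 0.25),
    oil_and_gas = list(depth = 0.25, trough = 5, rebound = 0.15),
    vcp = list(depth = 0.15, trough = 4, rebound = 0.5),
    point = list(depth = 0.2, trough = 4, rebound = 0.3)))
  for (inv in list(base, apply_monthly_scaling(base, act))) {
    nat <- aggregate(value ~ species + month, inv, sum)
    st <- aggregate(value ~ species + month, aggregate(
      value ~ species + state + month, inv, sum), sum)
    sec <- aggregate(value ~ species + month, aggregate(
      value ~ species + sector + month, inv, sum), sum)
    m1 <- merge(nat, st, by = c("species", "month"))
    m2 <- merge(nat, sec, by = c("species", "month"))
    expect_equal(m1$value.x, m1$value.y, tolerance = 1e-12)
    expect_equal(m2$value.x, m2$value.y, tolerance = 1e-12)
  }
})

test_that("round trip recovers the scalings for single-sector groups", {
  withr::with_seed(42, {
    g <- expand.grid(species = c("NOx", "VOC", "SO2"),
                     sector = c("s1", "s2", "s3"),
                     state = c("CA", "TX"), month = 1:2,
                     stringsAsFactors = FALSE)
    g$value <- runif(nrow(g), 1, 100)
    base <- suppressWarnings(emission_inventory(g))
    series <- expand.grid(sector = c("s1", "s2", "s3"), month = 1:2,
                          stringsAsFactors = FALSE)
    series$scaling <- runif(nrow(series), 0.3, 1.2)
    ch <- fractional_change(apply_monthly_scaling(base, series), base)
    m <- merge(ch$sector, series, by = c("sector", "month"))
    expect_equal(m$fraction, m$scaling - 1, tolerance = 1e-12)
  })
})

test_that("scaling monotonicity: lowering one sector's factor cannot raise a fraction", {
  base <- toy_inventory()
  series <- data.frame(sector = rep(c("onroad_gasoline", "point"), each = 2),
                       month = rep(c(4, 5), 2), scaling = c(0.8, 0.9, 1, 1))
  lower <- series; lower$scaling[1] <- 0.5
  ch_hi <- fractional_change(apply_monthly_scaling(base, series), base)
  ch_lo <- fractional_change(apply_monthly_scaling(base, lower), base)
  expect_true(all(ch_lo$national$fraction <= ch_hi$national$fraction + 1e-15))
})

test_that("state percentile band uses linear interpolation between order statistics", {
  fr <- c(-0.1, -0.2, -0.3, -0.4, -0.5)
  base <- emission_inventory(data.frame(
    species = "NOx", sector = "s", state = paste0("S", 1:5),
    month = 4, value = 100))
  scaled <- base; scaled$value <- 100 * (1 + fr)
  band <- state_percentile_band(fractional_change(scaled, base), "NOx", 4)
  expect_equal(band[["lo_pct"]], -0.42)
  expect_equal(band[["hi_pct"]], -0.18)
  # equal states: band collapses onto the common fraction
  eq <- base; eq$value <- 90
  band_eq <- state_percentile_band(fractional_change(eq, base), "NOx", 4)
  expect_equal(unname(band_eq), rep(-0.1, 3))
  expect_error(state_percentile_band(fractional_change(
    emission_inventory(data.frame(species = "NOx", sector = "s", state = "CA",
                                  month = 4, value = 1)),
    emission_inventory(data.frame(species = "NOx", sector = "s", state = "CA",
                                  month = 4, value = 2))), "NOx", 4),
    "at least 2 states")
})

test_that("a dominant state can drag the national value outside the band", {
  base <- emission_inventory(data.frame(
    species = "VOC", sector = "oil_and_gas", state = c("TX", "VT"),
    month = 5, value = c(1000, 1)))
  scaled <- base; scaled$value <- c(600, 1)   # -40% in the big emitter only
  band <- state_percentile_band(fractional_change(scaled, base), "VOC", 5)
  expect_lt(band[["national"]], band[["lo_pct"]])
})

test_that("period mean change is mass-weighted with state-variability sd", {
  # two months with equal reference mass and fractions -0.1 / -0.3
  base <- emission_inventory(data.frame(
    species = "NOx", sector = "s", state = c("CA", "CA"), month = c(4, 5),
    value = c(100, 100)))
  scaled <- base; scaled$value <- c(90, 70)
  ch <- fractional_change(scaled, base)
  pm <- period_mean_change(ch, "NOx", 4:5)
  expect_equal(pm[["mean"]], -0.2)
  expect_equal(pm[["sd"]], 0)    # single state, by convention
  # constant fraction across states and months: (f, 0)
  base2 <- emission_inventory(data.frame(
    species = "NOx", sector = "s", state = rep(c("CA", "TX"), 2),
    month = rep(4:5, each = 2), value = 50))
  scaled2 <- base2; scaled2$value <- 40
  pm2 <- period_mean_change(fractional_change(scaled2, base2), "NOx", 4:5)
  expect_equal(pm2[["mean"]], -0.2)
  expect_equal(pm2[["sd"]], 0)
  expect_error(period_mean_change(ch, "NOx", integer(0)), "non-empty")
})
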