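test_that("degenerate deterministic configuration yields a constant field", {
  g <- toy_grid()
  cfg <- scenario_config(noise_sd = 0, diurnal_amplitude = 0,
                         seasonal_amplitude = 0, o3_background = 40,
                         o3_enhancement = 10, monthly_reduction = rep(0, 12))
  f <- generate_scenario_fields(g, list(cfg), n_days = 3)[[1]]
  # flat pattern would need enhancement_pattern == 1 everywhere; instead
  # check the exact deterministic composition cell-wise
  expected <- 40 + 10 * enhancement_pattern(g)
  for (cell in seq_len(n_cells(g))) {
    expect_equal(unique(f$o3$values[, cell]), expected[cell])
  }
})

test_that("generators are bit-reproducible under identical arguments", {
  g <- toy_grid()
  cfg <- scenario_config(noise_sd = 4, seed = 7L)
  f1 <- generate_scenario_fields(g, list(cfg), n_days = 4)[[1]]
  f2 <- generate_scenario_fields(g, list(cfg), n_days = 4)[[1]]
  expect_identical(f1$o3$values, f2$o3$values)
  expect_identical(f1$pm25$values, f2$pm25$values)

  p1 <- generate_population(g, n_centers = 3, seed = 11L)
  p2 <- generate_population(g, n_centers = 3, seed = 11L)
  expect_identical(p1$values, p2$values)

  m1 <- generate_mortality(g, n_counties = 4, seed = 5L)
  m2 <- generate_mortality(g, n_counties = 4, seed = 5L)
  expect_identical(m1$values, m2$values)

  s1 <- generate_satellite_scene(rep(1e15, n_cells(g)), g, n_pixels = 20, seed = 3L)
  s2 <- generate_satellite_scene(rep(1e15, n_cells(g)), g, n_pixels = 20, seed = 3L)
  expect_identical(s1$pixels, s2$pixels)
})

test_that("met noise stream depends on met_year only, emission term on scenario only", {
  g <- toy_grid()
  red <- c(0, 0, 0, 0.4, 0.3, 0.2, rep(0.1, 6))
  bau <- scenario_config(met_year = "mA", scenario = "BAU", noise_sd = 5,
                         o3_background = 60, seed = 2L)
  cov <- scenario_config(met_year = "mA", scenario = "COV", noise_sd = 5,
                         o3_background = 60, monthly_reduction = red, seed = 2L)
  f <- generate_scenario_fields(g, list(bau, cov), n_days = 365)
  enh <- cov$o3_enhancement * enhancement_pattern(g)
  mon <- month_of_day(rep(1:365, each = 24), 4L)
  injected <- outer(red[mon], enh)
  # shared noise cancels exactly in the paired difference
  expect_equal(f[["mA.BAU"]]$o3$values - f[["mA.COV"]]$o3$values, injected,
               tolerance = 1e-12)
})

test_that("AR(1) met noise has the stated variance of the sample mean", {
  g <- grid_spec(1, 1)
  rho <- 0.6; sd_n <- 5; n_h <- 8760
  cfg <- scenario_config(noise_sd = sd_n, ar1_rho = rho, diurnal_amplitude = 0,
                         seasonal_amplitude = 0, o3_background = 100,
                         o3_enhancement = 0, seed = 31L)
  f <- generate_scenario_fields(g, list(cfg), n_days = 365)[[1]]
  resid <- f$o3$values[, 1] - 100
  se <- sd_n / sqrt(n_h * (1 - rho) / (1 + rho))
  expect_lt(abs(mean(resid)), 4 * se)
  # marginal sd close to the configured value
  expect_equal(sd(resid), sd_n, tolerance = 0.1)
})

test_that("a perturbed scenario without a BAU partner is rejected", {
  g <- toy_grid()
  cov <- scenario_config(met_year = "mX", scenario = "COV",
                         monthly_reduction = rep(0.1, 12))
  expect_error(generate_scenario_fields(g, list(cov), n_days = 2),
               "BAU partner")
  expect_error(scenario_config(diurnal_amplitude = -1), "non-negative")
  expect_error(scenario_config(scenario = "BAU",
                               monthly_reduction = rep(0.1, 12)),
               "identically zero")
})

test_that("population grid is normalised, non-negative and uniform in the flat limit", {
  g <- toy_grid(5, 6)
  pop <- generate_population(g, n_centers = 4, total = 1e6, seed = 9L)
  expect_true(all(pop$values >= 0))
  expect_equal(sum(pop$values), 1e6)
  flat <- generate_population(g, n_centers = 1, total = 3e5, decay = 0,
                              dispersion = 0, seed = 1L)
  expect_equal(flat$values, rep(3e5 / n_cells(g), n_cells(g)))
})

test_that("mortality counties tile the grid with one rate per county", {
  g <- grid_spec(6, 8)
  m <- generate_mortality(g, n_counties = 6, mean_rate = 0.01,
                          sd_rate = 0.003, seed = 4L)
  expect_equal(sort(unique(m$county_id)), 1:6)
  for (cid in unique(m$county_id)) {
    expect_length(unique(m$values[m$county_id == cid]), 1)
  }
  expect_true(all(m$values > 0 & m$values < 1))
  const <- generate_mortality(g, n_counties = 4, mean_rate = 0.008,
                              sd_rate = 0, seed = 1L)
  expect_equal(unique(const$values), 0.008)
  single <- generate_mortality(g, n_counties = 1, mean_rate = 0.008,
                               sd_rate = 0.001, seed = 1L)
  expect_equal(unique(single$county_id), 1L)
})

test_that("county rates average to the configured mean within a CLT bound", {
  g <- grid_spec(10, 10)
  n_c <- 25; mu <- 0.009; s <- 0.002
  m <- generate_mortality(g, n_counties = n_c, mean_rate = mu, sd_rate = s,
                          seed = 17L)
  county_rates <- tapply(m$values, m$county_id, unique)
  expect_lt(abs(mean(county_rates) - mu), 4 * s / sqrt(n_c))
})

test_that("activity series honour depth, trough and rebound", {
  act <- generate_activity(list(
    gasoline = list(depth = 0.4, trough = 4, rebound = 0.3),
    flat = list(depth = 0, trough = 4, rebound = 0.3),
    frozen = list(depth = 0.25, trough = 4, rebound = 0)))
  gas <- act$scaling[act$sector == "gasoline"]
  expect_equal(gas[4], 0.6)                      # 40% April trough
  expect_true(all(diff(gas[4:12]) > 0))          # relaxation toward 1
  expect_equal(act$scaling[act$sector == "flat"], rep(1, 12))
  froz <- act$scaling[act$sector == "frozen"]
  expect_equal(froz[4:12], rep(0.75, 9))         # no rebound
  expect_error(generate_activity(list(bad = list(depth = 1.2, trough = 4,
                                                 rebound = 0))),
               "depth")
})

test_that("satellite scenes are self-consistent and unbiased", {
  g <- toy_grid()
  cols <- 2e15 * enhancement_pattern(g) + 1e14
  # noise-free, a priori equal to model shape: pixel column = model column
  s0 <- generate_satellite_scene(cols, g, n_pixels = 50, noise = 0,
                                 apriori_deviation = 0, seed = 6L)
  expect_equal(s0$pixels$vcd, cols[s0$pixels$cell], tolerance = 1e-12)
  expect_equal(s0$apriori, s0$model_profile, tolerance = 1e-12)
  # amf_orig is self-consistent with (scattering weights, a priori)
  s <- generate_satellite_scene(cols, g, n_pixels = 200, noise = 0.1, seed = 8L)
  amf_check <- rowSums(s$scattering_weights * s$apriori) / rowSums(s$apriori)
  expect_equal(s$pixels$amf_orig, amf_check, tolerance = 1e-12)
  # CLT: mean relative column error near zero over many pixels
  noise <- 0.1; n_px <- 10000
  sl <- generate_satellite_scene(cols, g, n_pixels = n_px, noise = noise,
                                 seed = 12L)
  rel_err <- sl$pixels$vcd / cols[sl$pixels$cell] - 1
  expect_lt(abs(mean(rel_err)), 4 * noise / sqrt(n_px))
})
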