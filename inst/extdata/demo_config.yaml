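# Desk-scale demonstration configuration (see ?default_config for the
# meaning and units of every block).
seed: 1
grid:
  n_lat: 20
  n_lon: 30
  lat0: 30.0
  lon0: -110.0
  dlat: 0.5
  dlon: 0.5
n_days: 120
start_month: 4
met_years:
  bau_alt: met2019
  main: met2020
activity_profiles:
  onroad_gasoline: {depth: 0.40, trough: 4, rebound: 0.30}
  onroad_diesel: {depth: 0.20, trough: 4, rebound: 0.25}
  nonroad: {depth: 0.25, trough: 4, rebound: 0.25}
  oil_and_gas: {depth: 0.25, trough: 5, rebound: 0.15}
  vcp: {depth: 0.15, trough: 4, rebound: 0.50}
  point: {depth: 0.20, trough: 4, rebound: 0.30}
o3:
  background: 30.0     # ppb
  enhancement: 12.0    # ppb at the pattern peak
  diurnal: 8.0         # ppb
  seasonal: 10.0       # ppb
  rho: 0.6
  noise_sd: 5.0        # ppb
pm25:
  median: 8.0          # ug m-3
  gsd: 1.6
  anthro_frac: 0.35
population:
  n_centers: 8
  total: 3.3e+08
  decay: 25.0
  dispersion: 0.5
mortality:
  n_counties: 24
  mean_rate: 0.009     # deaths / person / yr
  sd_rate: 0.002
satellite:
  n_pixels: 2000
  noise: 0.1
  apriori_deviation: 0.3
  n_layers: 12
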