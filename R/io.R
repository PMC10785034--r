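# Plain-text I/O. Gridded objects are written as long-format CSV with
# `#key: value` metadata header lines (units, grid geometry, tags) so every
# file is self-describing; numeric values use 17 significant digits so a
# round trip reproduces the in-memory doubles exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_meta_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("#%s: %s", k, meta[[k]]), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[cumsum(!is_meta) == 0 & is_meta]
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#", "", l)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- sub("^[^:]*: ?", "", kv)
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  list(meta = meta, data = df)
}

grid_meta <- function(grid) {
  list(n_lat = grid$n_lat, n_lon = grid$n_lon, lat0 = fmt_num(grid$lat0),
       lon0 = fmt_num(grid$lon0), dlat = fmt_num(grid$dlat),
       dlon = fmt_num(grid$dlon))
}

grid_from_meta <- function(meta) {
  grid_spec(as.integer(meta$n_lat), as.integer(meta$n_lon),
            as.numeric(meta$lat0), as.numeric(meta$lon0),
            as.numeric(meta$dlat), as.numeric(meta$dlon))
}

#' Write / read a concentration field as CSV
#'
#' Long format (`time`, `cell`, `value`) with metadata header lines carrying
#' the grid geometry, pollutant, cadence, units and scenario tags. Re-reading
#' reproduces the in-memory values exactly.
#'
#' @param field An [concentration_field()].
#' @param path Output path.
#' @export
write_field_csv <- function(field, path) {
  v <- field$values
  df <- data.frame(time = rep(seq_len(nrow(v)), ncol(v)),
                   cell = rep(seq_len(ncol(v)), each = nrow(v)),
                   value = as.numeric(v))
  meta <- c(list(type = "concentration_field", pollutant = field$pollutant,
                 cadence = field$cadence, units = field$units,
                 met_year = field$met_year, scenario = field$scenario,
                 start_month = field$start_month,
                 n_time = nrow(v)), grid_meta(field$grid))
  write_meta_csv(df, path, meta)
}

#' @rdname write_field_csv
#' @return `read_field_csv` returns the reconstructed `aq_field`.
#' @export
read_field_csv <- function(path) {
  r <- read_meta_csv(path)
  grid <- grid_from_meta(r$meta)
  n_time <- as.integer(r$meta$n_time)
  v <- matrix(NA_real_, n_time, n_cells(grid))
  v[cbind(r$data$time, r$data$cell)] <- r$data$value
  concentration_field(v, grid, r$meta$pollutant, r$meta$cadence,
                      met_year = r$meta$met_year, scenario = r$meta$scenario,
                      units = r$meta$units,
                      start_month = as.integer(r$meta$start_month))
}

#' Write / read an exposure surface as CSV
#'
#' @param surface An [exposure_surface()].
#' @param path Output path.
#' @export
write_surface_csv <- function(surface, path) {
  df <- data.frame(cell = seq_along(surface$values), value = surface$values)
  meta <- c(list(type = "exposure_surface", metric = surface$metric,
                 units = surface$units, window = surface$window,
                 met_year = surface$met_year, scenario = surface$scenario),
            grid_meta(surface$grid))
  write_meta_csv(df, path, meta)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  r <- read_meta_csv(path)
  grid <- grid_from_meta(r$meta)
  v <- rep(NA_real_, n_cells(grid))
  v[r$data$cell] <- r$data$value
  exposure_surface(v, grid, metric = r$meta$metric, units = r$meta$units,
                   window = r$meta$window, met_year = r$meta$met_year,
                   scenario = r$meta$scenario)
}

#' Write / read an emission inventory as CSV
#'
#' Columns `species`, `sector`, `state`, `month`, `value` (t/month), with
#' the base year in the metadata header.
#'
#' @param inv An [emission_inventory()].
#' @param path Output path.
#' @export
write_inventory_csv <- function(inv, path) {
  write_meta_csv(as.data.frame(inv), path,
                 list(type = "emission_inventory", units = "t month-1",
                      base_year = attr(inv, "base_year")))
}

#' @rdname write_inventory_csv
#' @export
read_inventory_csv <- function(path) {
  r <- read_meta_csv(path)
  emission_inventory(r$data, base_year = r$meta$base_year)
}

#' Write / read a satellite scene as CSV
#'
#' One row per pixel; the layered scattering-weight, a priori and model
#' profiles are stored as wide column blocks `sw_1..sw_L`, `ap_1..ap_L`,
#' `mp_1..mp_L`.
#'
#' @param scene An `aq_scene`.
#' @param path Output path.
#' @export
write_scene_csv <- function(scene, path) {
  L <- scene$n_layers
  wide <- cbind(scene$pixels,
                stats::setNames(as.data.frame(scene$scattering_weights),
                                paste0("sw_", seq_len(L))),
                stats::setNames(as.data.frame(scene$apriori),
                                paste0("ap_", seq_len(L))),
                stats::setNames(as.data.frame(scene$model_profile),
                                paste0("mp_", seq_len(L))))
  meta <- c(list(type = "retrieval_scene", n_layers = L,
                 units_vcd = "molec cm-2"), grid_meta(scene$grid))
  write_meta_csv(wide, path, meta)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  r <- read_meta_csv(path)
  L <- as.integer(r$meta$n_layers)
  d <- r$data
  block <- function(prefix)
    as.matrix(d[paste0(prefix, seq_len(L))])
  px_cols <- setdiff(names(d), c(paste0("sw_", 1:L), paste0("ap_", 1:L),
                                 paste0("mp_", 1:L)))
  structure(list(pixels = d[px_cols], scattering_weights = unname(block("sw_")),
                 apriori = unname(block("ap_")),
                 model_profile = unname(block("mp_")),
                 grid = grid_from_meta(r$meta), n_layers = L),
            class = "aq_scene")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file; see
#'   [default_config()] for the accepted structure.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
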