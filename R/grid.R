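#' Regular latitude-longitude grid specification
#'
#' Defines the common analysis grid shared by every gridded object in a run:
#' concentration fields, exposure surfaces, population, baseline mortality and
#' region labels. Cell centres are at `lat0 + (i-1)*dlat`, `lon0 + (j-1)*dlon`.
#' Cells are indexed column-major with latitude varying fastest, so cell
#' `k = (j-1)*n_lat + i`.
#'
#' @param n_lat,n_lon Number of grid cells along latitude and longitude.
#' @param lat0,lon0 Centre coordinates (degrees) of the first cell.
#' @param dlat,dlon Cell spacing in degrees; must be positive.
#' @return An object of class `aq_grid`.
#' @examples
#' g <- grid_spec(4, 5)
#' n_cells(g)
#' @export
grid_spec <- function(n_lat, n_lon, lat0 = 30, lon0 = -110,
                      dlat = 0.5, dlon = 0.5) {
  if (n_lat < 1 || n_lon < 1) stop("n_lat and n_lon must be >= 1")
  if (dlat <= 0 || dlon <= 0) stop("dlat and dlon must be > 0")
  structure(list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 lat0 = lat0, lon0 = lon0, dlat = dlat, dlon = dlon),
            class = "aq_grid")
}

#' @rdname grid_spec
#' @param grid An `aq_grid`.
#' @export
n_cells <- function(grid) grid$n_lat * grid$n_lon

#' @rdname grid_spec
#' @export
grid_lats <- function(grid) grid$lat0 + (seq_len(grid$n_lat) - 1) * grid$dlat

#' @rdname grid_spec
#' @export
grid_lons <- function(grid) grid$lon0 + (seq_len(grid$n_lon) - 1) * grid$dlon

#' Cell index containing a point
#'
#' Maps a latitude/longitude to the index of the nearest cell centre
#' (equivalently, the cell whose bounds contain the point). Points outside
#' the domain (beyond half a cell from the outermost centres) are an error.
#'
#' @param grid An `aq_grid`.
#' @param lat,lon Coordinates in degrees (vectorised).
#' @return Integer cell indices (column-major, latitude fastest).
#' @export
cell_of <- function(grid, lat, lon) {
  i <- round((lat - grid$lat0) / grid$dlat) + 1
  j <- round((lon - grid$lon0) / grid$dlon) + 1
  bad <- i < 1 | i > grid$n_lat | j < 1 | j > grid$n_lon
  if (any(bad)) {
    stop(sprintf("%d point(s) fall outside the grid domain", sum(bad)))
  }
  as.integer((j - 1) * grid$n_lat + i)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(sprintf("grid mismatch between %s", what))
  invisible(TRUE)
}

#' @export
print.aq_grid <- function(x, ...) {
  cat(sprintf("<aq_grid> %d x %d cells, origin (%.3f, %.3f), spacing (%.3f, %.3f) deg\n",
              x$n_lat, x$n_lon, x$lat0, x$lon0, x$dlat, x$dlon))
  invisible(x)
}
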