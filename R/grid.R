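#' Regular longitude/latitude grid specification
#'
#' Cell-centre registered regular grid. Cells are ordered row-major with
#' ascending latitude first, then ascending longitude within each row, so cell
#' `k` sits at row `(k - 1) %/% nx + 1` (latitude) and column
#' `(k - 1) %% nx + 1` (longitude).
#'
#' @param lon_min,lon_max,lat_min,lat_max domain bounds in degrees.
#' @param cell_size cell edge length in degrees; the spans must be integer
#'   multiples of it.
#' @return an object of class `grid_spec` with elements `nx`, `ny`, `n_cells`,
#'   `lon` (cell-centre longitudes, length `nx`) and `lat` (length `ny`).
#' @examples
#' g <- grid_spec(-10, 45, 27, 55, 0.1)
#' g$n_cells # 154000
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell_size > 0)
  nx <- (lon_max - lon_min) / cell_size
  ny <- (lat_max - lat_min) / cell_size
  if (abs(nx - round(nx)) > 1e-6 || abs(ny - round(ny)) > 1e-6)
    stop("grid spans must be integer multiples of cell_size")
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  g <- list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    cell_size = cell_size, nx = nx, ny = ny,
    n_cells = nx * ny,
    lon = lon_min + cell_size * (seq_len(nx) - 0.5),
    lat = lat_min + cell_size * (seq_len(ny) - 0.5)
  )
  class(g) <- "grid_spec"
  g
}

#' Cell-centre coordinates of every grid cell
#'
#' @param grid a [grid_spec()].
#' @return data.frame with columns `cell`, `lon`, `lat` in cell order.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  data.frame(
    cell = seq_len(grid$n_cells),
    lon = rep(grid$lon, times = grid$ny),
    lat = rep(grid$lat, each = grid$nx)
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %g..%g E x %g..%g N @ %g deg (%d x %d = %d cells)\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max, x$cell_size,
              x$nx, x$ny, x$n_cells))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("lon_min", "lon_max", "lat_min", "lat_max",
                       "cell_size")],
                   b[c("lon_min", "lon_max", "lat_min", "lat_max",
                       "cell_size")]))
}

#' Great-circle distance between points (haversine)
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; recycled as usual.
#' @return distance in kilometres.
#' @export
gc_distance <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}
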