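#' Grid specification for the synthetic ocean
#'
#' Defines the lon/lat/depth/time grid on which all synthetic fields live,
#' together with the (constant, f-plane) Coriolis parameter and gravity.
#' Depth is positive down with the surface as the first level.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds in degrees. The
#'   default domain (49-37 W, 28.5-21.1 S) covers the Campos/Santos basin
#'   shelf break and the Cape Frio eddy corridor.
#' @param d_deg Horizontal grid step in degrees (default 1/12 degree,
#'   ~9 km, at least 8 points per eddy radius for a 30-70 km eddy).
#' @param depth_levels Depth levels in metres, positive down, strictly
#'   increasing from 0.
#' @param t_days Number of daily field snapshots.
#' @param lat_f Reference latitude (degrees) for the f-plane.
#' @param g Gravitational acceleration, m s^-2.
#' @return An object of class `grid_spec`: list with `lon`, `lat` axis
#'   vectors, `depth`, `t_days`, `d_deg`, `f` (s^-1, negative in the
#'   Southern Hemisphere) and `g`.
#' @export
grid_spec <- function(lon_min = -49, lon_max = -37,
                      lat_min = -28.5, lat_max = -21.1,
                      d_deg = 1 / 12,
                      depth_levels = c(0, 5, 10, 20, 30, 40, 60, 80,
                                       100, 150, 300, 600),
                      t_days = 30, lat_f = -23.5, g = 9.81) {
  stopifnot(d_deg > 0, lon_max > lon_min, lat_max > lat_min, t_days >= 1)
  if (length(depth_levels) < 2 || depth_levels[1] != 0 ||
      any(diff(depth_levels) <= 0)) {
    stop("depth_levels must be strictly increasing from 0")
  }
  lon <- seq(lon_min, lon_max, by = d_deg)
  lat <- seq(lat_min, lat_max, by = d_deg)
  if (length(lon) < 2 || length(lat) < 2) {
    stop("degenerate grid: fewer than 2 rows or columns")
  }
  f <- 2 * 7.2921e-5 * sin(lat_f * pi / 180)
  if (f == 0) stop("f-plane latitude of 0 gives f = 0; geostrophy undefined")
  structure(list(lon = lon, lat = lat, depth = depth_levels,
                 t_days = as.integer(t_days), d_deg = d_deg,
                 f = f, g = g),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d grid, %d daily snapshots\n",
              length(x$lon), length(x$lat), length(x$depth), x$t_days))
  cat(sprintf("  lon %.2f..%.2f, lat %.2f..%.2f, step %.4f deg\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat), x$d_deg))
  cat(sprintf("  depth 0..%g m (%d levels), f = %.4g s^-1\n",
              max(x$depth), length(x$depth), x$f))
  invisible(x)
}

# Mean Earth radius used for every great-circle computation in the package
# (distances, destination points, degree<->metre conversions).
EARTH_RADIUS_M <- 6371000

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6371 km. Thin wrapper around
#' [geosphere::distHaversine()] pinning the Earth radius so that all
#' package distances share one convention (1 degree of latitude =
#' 111.19 km).
#'
#' @param p1,p2 Two-column matrices (or length-2 vectors) of lon, lat in
#'   degrees; recycled against each other.
#' @return Distance(s) in metres.
#' @export
gc_distance <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
}

#' Destination point along a bearing
#'
#' @param p Starting point(s), lon/lat degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param distance Distance in metres.
#' @return Matrix of lon, lat.
#' @export
gc_destination <- function(p, bearing, distance) {
  geosphere::destPoint(p, bearing, distance, r = EARTH_RADIUS_M)
}

# metres per degree of longitude/latitude at latitude phi (degrees)
m_per_deg_lon <- function(lat) EARTH_RADIUS_M * pi / 180 * cos(lat * pi / 180)
m_per_deg_lat <- function(lat) rep(EARTH_RADIUS_M * pi / 180, length(lat))

# Local equirectangular projection about (lon0, lat0): returns km
local_xy_km <- function(lon, lat, lon0, lat0) {
  cbind(x = (lon - lon0) * m_per_deg_lon(lat0) / 1000,
        y = (lat - lat0) * m_per_deg_lat(lat0) / 1000)
}
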