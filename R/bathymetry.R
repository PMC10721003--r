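#' Synthetic shelf-slope bathymetry
#'
#' Builds a smooth bathymetry that deepens monotonically offshore from a
#' synthetic coastline: a linear shelf reaching 200 m at `shelf_width_km`,
#' a cosine-smoothed continental slope reaching `max_depth_m` over a
#' further `slope_width_km`, then a flat abyssal plain. The 200 m and
#' 1000 m isobaths (the coastal-barrier criterion and the jet-core anchor)
#' are therefore at controlled distances from the coast.
#'
#' @param grid A [grid_spec()].
#' @param coast Two-column matrix of (lon, lat) vertices of the coastline
#'   polyline, ordered so that offshore lies to the right of the direction
#'   of travel. Default: a schematic Rio de Janeiro coastline turning at
#'   Cape Frio.
#' @param shelf_width_km Width of the 0-200 m shelf.
#' @param slope_width_km Width of the 200 m-`max_depth_m` slope.
#' @param max_depth_m Abyssal depth.
#' @return List of class `bathymetry`: `h` (matrix, metres, dims lon x lat,
#'   0 on land/coast), `coast_dist` (signed distance to coast in km,
#'   positive offshore), `coast`, and the ramp parameters.
#' @export
build_bathymetry <- function(grid,
                             coast = default_coastline(),
                             shelf_width_km = 90,
                             slope_width_km = 60,
                             max_depth_m = 3000) {
  stopifnot(inherits(grid, "grid_spec"),
            shelf_width_km > 0, slope_width_km > 0, max_depth_m > 200)
  if (length(grid$lon) < 2 || length(grid$lat) < 2) {
    stop("degenerate grid: fewer than 2 rows or columns")
  }
  pts <- expand.grid(lon = grid$lon, lat = grid$lat)
  d <- signed_coast_distance_km(pts$lon, pts$lat, coast)
  h <- depth_ramp(d, shelf_width_km, slope_width_km, max_depth_m)
  structure(list(h = matrix(h, nrow = length(grid$lon)),
                 coast_dist = matrix(d, nrow = length(grid$lon)),
                 coast = coast,
                 shelf_width_km = shelf_width_km,
                 slope_width_km = slope_width_km,
                 max_depth_m = max_depth_m),
            class = "bathymetry")
}

#' Schematic coastline used by the reference scenario
#'
#' Runs roughly west-east at ~23 S and turns north-eastward at Cape Frio,
#' mimicking the change of coastline orientation that makes the region's
#' mesoscale so active. Offshore is the right-hand side walking the
#' polyline from west to east.
#' @return Two-column matrix of lon, lat.
#' @export
default_coastline <- function() {
  cbind(lon = c(-49.0, -44.5, -42.6, -41.4, -40.2, -38.8),
        lat = c(-23.30, -22.85, -22.70, -21.90, -20.90, -19.80))
}

# depth profile as a function of signed offshore distance (km)
depth_ramp <- function(d, shelf_w, slope_w, max_d) {
  h <- numeric(length(d))
  on_shelf <- d > 0 & d <= shelf_w
  on_slope <- d > shelf_w & d <= shelf_w + slope_w
  abyss <- d > shelf_w + slope_w
  h[on_shelf] <- 200 * d[on_shelf] / shelf_w
  frac <- (d[on_slope] - shelf_w) / slope_w
  h[on_slope] <- 200 + (max_d - 200) * (1 - cos(pi * frac)) / 2
  h[abyss] <- max_d
  h
}

# Signed distance (km) from points to the coastline polyline: positive on
# the offshore (right-hand) side. Planar approximation about the domain
# centre; adequate for a synthetic coast at these scales.
signed_coast_distance_km <- function(lon, lat, coast) {
  lon0 <- mean(range(coast[, 1])); lat0 <- mean(range(coast[, 2]))
  p <- local_xy_km(lon, lat, lon0, lat0)
  v <- local_xy_km(coast[, 1], coast[, 2], lon0, lat0)
  n <- nrow(v)
  best <- rep(Inf, nrow(p)); side <- rep(1, nrow(p))
  for (i in seq_len(n - 1)) {
    a <- v[i, ]; b <- v[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
    di <- sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2)
    # right of travel direction = negative cross product z-component
    cr <- ab[1] * (p[, 2] - a[2]) - ab[2] * (p[, 1] - a[1])
    upd <- di < best
    best[upd] <- di[upd]
    side[upd] <- ifelse(cr[upd] < 0, 1, -1)
  }
  best * side
}

#' Offshore distance at which the bathymetry crosses a given isobath
#'
#' Inverts the analytic depth ramp; used to anchor the jet axis on the
#' 1000 m isobath and in tests of the mid-slope ramp value.
#' @param bathy A [build_bathymetry()] result (or a list with the ramp
#'   parameters).
#' @param depth_m Isobath depth in metres (0 < depth < max depth).
#' @return Distance from the coast in km.
#' @export
isobath_distance_km <- function(bathy, depth_m) {
  stopifnot(depth_m > 0, depth_m < bathy$max_depth_m)
  if (depth_m <= 200) {
    bathy$shelf_width_km * depth_m / 200
  } else {
    frac <- acos(1 - 2 * (depth_m - 200) / (bathy$max_depth_m - 200)) / pi
    bathy$shelf_width_km + bathy$slope_width_km * frac
  }
}

# Bilinear bathymetry lookup (metres) at arbitrary lon/lat
bathy_at <- function(bathy, grid, lon, lat) {
  interp_bilinear(bathy$h, grid$lon, grid$lat, lon, lat)
}
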