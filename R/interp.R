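# Interpolation of gridded fields at particle positions.
#
# Trilinear in (lon, lat, depth), linear in time between daily snapshots
# (clamped at the ends of the record). Exact for fields linear in each
# coordinate. Depth queries below the deepest level clamp to it; lateral
# queries outside the hull are the caller's responsibility (the float
# model treats them as a domain exit before ever interpolating).

# fractional-index weights along one axis (clamped to the hull)
axis_weights <- function(v, x) {
  i <- findInterval(x, v, all.inside = TRUE)
  w <- (x - v[i]) / (v[i + 1] - v[i])
  list(i = i, w = pmin(1, pmax(0, w)))
}

trilinear_weights <- function(xv, yv, zv, x, y, z) {
  list(x = axis_weights(xv, x), y = axis_weights(yv, y),
       z = axis_weights(zv, z), nx = length(xv), ny = length(yv),
       nz = length(zv))
}

# evaluate one 3-D slab (x,y,z) of a 4-D array at snapshot it using
# precomputed weights; arr is indexed as a flat vector for speed
gather3 <- function(arr, tw, it, nx, ny, nz) {
  off <- (it - 1L) * nx * ny * nz
  ix <- tw$x$i; iy <- tw$y$i; iz <- tw$z$i
  wx <- tw$x$w; wy <- tw$y$w; wz <- tw$z$w
  base <- off + ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
  dz <- nx * ny
  c00 <- arr[base] * (1 - wx) + arr[base + 1L] * wx
  c10 <- arr[base + nx] * (1 - wx) + arr[base + nx + 1L] * wx
  c01 <- arr[base + dz] * (1 - wx) + arr[base + dz + 1L] * wx
  c11 <- arr[base + dz + nx] * (1 - wx) + arr[base + dz + nx + 1L] * wx
  (c00 * (1 - wy) + c10 * wy) * (1 - wz) + (c01 * (1 - wy) + c11 * wy) * wz
}

# time weights for a daily-snapshot record (a single snapshot is constant
# in time)
time_weights <- function(days, tau) {
  if (length(days) == 1L) return(list(i = 1L, w = 0))
  it <- findInterval(tau, days, all.inside = TRUE)
  wt <- (tau - days[it]) / (days[it + 1] - days[it])
  list(i = it, w = min(1, max(0, wt)))
}

#' Interpolate velocity (and any 4-D field) at particle positions
#'
#' @param state An [ocean_state()].
#' @param vars Character vector of 4-D variables to interpolate
#'   (subset of `u`, `v`, `w`, `temp`).
#' @param lon,lat,z Particle coordinates (vectors of equal length); depth
#'   positive down, m.
#' @param tau Scalar time in days (the float model advances all particles
#'   synchronously).
#' @return Named list of interpolated vectors.
#' @export
interp_fields <- function(state, vars, lon, lat, z, tau) {
  g <- state$grid
  tw <- trilinear_weights(g$lon, g$lat, g$depth, lon, lat, z)
  ts <- time_weights(state$days, tau)
  nx <- tw$nx; ny <- tw$ny; nz <- tw$nz
  out <- vector("list", length(vars)); names(out) <- vars
  for (v in vars) {
    arr <- state[[v]]
    a <- gather3(arr, tw, ts$i, nx, ny, nz)
    b <- if (ts$w > 0) gather3(arr, tw, ts$i + 1L, nx, ny, nz) else a
    out[[v]] <- a * (1 - ts$w) + b * ts$w
  }
  out
}

#' Interpolate the horizontal+vertical velocity at particle positions
#'
#' Convenience wrapper used by the float model; positions outside the grid
#' hull are an error here (the caller flags exits first).
#' @inheritParams interp_fields
#' @return List with `u`, `v`, `w` vectors (m/s).
#' @export
interp_velocity <- function(state, lon, lat, z, tau) {
  g <- state$grid
  if (any(lon < g$lon[1] | lon > g$lon[length(g$lon)] |
          lat < g$lat[1] | lat > g$lat[length(g$lat)])) {
    stop("interp_velocity: position outside the grid hull")
  }
  interp_fields(state, c("u", "v", "w"), lon, lat, z, tau)
}

# bilinear interpolation of a 2-D matrix (clamped to the hull)
interp_bilinear <- function(m, xv, yv, x, y) {
  ax <- axis_weights(xv, x); ay <- axis_weights(yv, y)
  nx <- length(xv)
  base <- ax$i + nx * (ay$i - 1L)
  mm <- as.vector(m)
  c0 <- mm[base] * (1 - ax$w) + mm[base + 1L] * ax$w
  c1 <- mm[base + nx] * (1 - ax$w) + mm[base + nx + 1L] * ax$w
  c0 * (1 - ay$w) + c1 * ay$w
}
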