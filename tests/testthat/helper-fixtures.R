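# Shared fixtures: small grids, analytic states, and a cached reference
# run (built once, reused by the acceptance tests).

small_grid <- function(t_days = 1, d_deg = 1 / 12) {
  grid_spec(lon_min = -44, lon_max = -40, lat_min = -26, lat_max = -22.5,
            d_deg = d_deg, depth_levels = c(0, 50, 100), t_days = t_days)
}

# a quiescent state (zero flow) on a small grid
still_state <- function(grid = small_grid()) {
  nx <- length(grid$lon); ny <- length(grid$lat)
  nz <- length(grid$depth); nt <- grid$t_days
  structure(list(grid = grid, days = seq_len(nt),
                 ssh = array(0, c(nx, ny, nt)),
                 u = array(0, c(nx, ny, nz, nt)),
                 v = array(0, c(nx, ny, nz, nt)),
                 w = array(0, c(nx, ny, nz, nt)),
                 temp = array(20, c(nx, ny, nz, nt)),
                 bathy_h = matrix(1000, nx, ny)),
            class = "ocean_state")
}

# uniform horizontal flow, m/s
uniform_state <- function(u = 0, v = 0, grid = small_grid()) {
  st <- still_state(grid)
  st$u[] <- u
  st$v[] <- v
  st
}

# a stationary circular Gaussian-depression scenario (no growth, no w)
static_eddy_scenario <- function(center, A = 0.1, L_km = 50, grid) {
  scen <- eddy_scenario(center0 = center, L0 = L_km, Linf = L_km,
                        growth_k = 0, U0 = 1, Uinf = 1,
                        stationary_days = 100, c_slow = 0, c_fast = 0,
                        w0 = 0, w_up = 0, dome_coef = 0,
                        f = grid$f, g = grid$g)
  scen$A_fixed <- A
  scen
}

# rescale an eddy-only state so the depression amplitude is exactly A
pin_amplitude <- function(state, A) {
  for (i in seq_along(state$days)) {
    state$ssh[, , i] <- state$ssh[, , i] * (A / max(-state$ssh[, , i]))
    uv <- geostrophic_velocity(state$ssh[, , i], state$grid)
    uv3 <- extend_velocity_vertical(uv$u, uv$v, state$grid$depth, 500)
    state$u[, , , i] <- uv3$u
    state$v[, , , i] <- uv3$v
  }
  state
}

# independent winding-number point-in-polygon oracle
winding_inside <- function(px, py, poly) {
  poly <- rbind(poly, poly[1, ])
  n <- nrow(poly) - 1
  vapply(seq_along(px), function(i) {
    ang <- 0
    for (k in seq_len(n)) {
      a <- atan2(poly[k, 2] - py[i], poly[k, 1] - px[i])
      b <- atan2(poly[k + 1, 2] - py[i], poly[k + 1, 1] - px[i])
      d <- b - a
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      ang <- ang + d
    }
    abs(ang) > pi
  }, logical(1))
}

# cached reference scenario run (scale 0.1, seed 1); built on first use
.ref_cache <- new.env(parent = emptyenv())
ref_bundle <- function() {
  if (is.null(.ref_cache$bundle)) {
    .ref_cache$bundle <- run_scenario(seed = 1, scale = 0.1)
  }
  .ref_cache$bundle
}
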