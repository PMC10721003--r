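test_that("eddy centre follows the integrated translation schedule", {
  scen <- eddy_scenario(stationary_days = 0, c_slow = 0.15, c_fast = 0.15)
  expect_equal(unname(eddy_center(scen, 0)[1, ]), scen$center0)
  # 0.15 m/s for 10 days: 129.6 km along the heading, hand-computed
  d <- gc_distance(scen$center0, eddy_center(scen, 10))
  expect_equal(d, 0.15 * 86400 * 10, tolerance = 1e-3)
  # zero translation keeps the centre fixed
  scen0 <- eddy_scenario(c_slow = 0, c_fast = 0, stationary_days = 40)
  expect_equal(unname(eddy_center(scen0, 25)[1, ]), scen0$center0)
  expect_error(eddy_center(scen, -1), "out of range")
})

test_that("SSH is additive and the depression follows the Gaussian closed form", {
  grid <- small_grid()
  ctr <- c(mean(grid$lon), mean(grid$lat))
  scen <- static_eddy_scenario(ctr, grid = grid)
  sch <- eddy_schedule(scen, 1)
  eta <- ssh_field(NULL, scen, grid, 1)
  # centre value is -A (exponential of zero)
  eta_c <- cfeddy:::interp_bilinear(eta, grid$lon, grid$lat, ctr[1], ctr[2])
  expect_equal(eta_c, -sch$A_m, tolerance = 1e-4 * sch$A_m)
  # at distance L the depression is -A exp(-1/2)
  pL <- gc_destination(ctr, 90, sch$L_km * 1000)
  eta_L <- cfeddy:::interp_bilinear(eta, grid$lon, grid$lat, pL[1], pL[2])
  expect_equal(eta_L, -sch$A_m * exp(-0.5), tolerance = 3e-3 * sch$A_m)
  # with no eddy the field equals the jet-only field
  bathy <- build_bathymetry(grid)
  jet <- jet_spec()
  expect_equal(ssh_field(jet, NULL, grid, 1, bathy),
               ssh_field(jet, scen, grid, 1, bathy) -
                 ssh_field(NULL, scen, grid, 1))
})

test_that("geostrophic balance: flat and linear SSH give the exact velocities", {
  grid <- small_grid()
  flat <- matrix(0.05, length(grid$lon), length(grid$lat))
  uv <- geostrophic_velocity(flat, grid)
  expect_equal(max(abs(uv$u)), 0)
  expect_equal(max(abs(uv$v)), 0)
  # eta = a * y: u = -(g/f) a, v = 0, exact for centred differences
  a <- 1e-6
  y <- outer(rep(1, length(grid$lon)),
             (grid$lat - grid$lat[1]) * cfeddy:::m_per_deg_lat(grid$lat))
  uv <- geostrophic_velocity(a * y, grid)
  expect_equal(uv$u, matrix(-(grid$g / grid$f) * a, nrow(y), ncol(y)),
               tolerance = 1e-10)
  expect_equal(max(abs(uv$v)), 0, tolerance = 1e-12)
  g0 <- grid; g0$f <- 0
  expect_error(geostrophic_velocity(flat, g0), "f = 0")
})

test_that("Gaussian eddy azimuthal speed matches the closed form within 2%", {
  st <- make_fixtures("gaussian-eddy")
  grid <- st$grid
  ctr <- c(mean(grid$lon), mean(grid$lat))
  A <- 0.1; L <- 50e3
  uv <- geostrophic_velocity(st$ssh[, , 1], grid)
  vmax_theory <- (grid$g / abs(grid$f)) * (A / L) * exp(-0.5)
  expect_equal(vmax_theory, 0.205, tolerance = 0.005)
  # sample at the grid nodes nearest each radius/bearing so only the
  # finite-difference truncation enters, and compare with the closed form
  # evaluated at the node's own radius
  sp_grid <- sqrt(uv$u^2 + uv$v^2)
  for (r_frac in c(0.2, 0.5, 1, 1.5, 2, 2.5)) {
    for (bear in c(0, 90, 225)) {
      p <- gc_destination(ctr, bear, r_frac * L)
      i <- which.min(abs(grid$lon - p[1]))
      j <- which.min(abs(grid$lat - p[2]))
      r_node <- gc_distance(ctr, c(grid$lon[i], grid$lat[j]))
      v_th <- (grid$g / abs(grid$f)) * (r_node / L^2) * A *
        exp(-r_node^2 / (2 * L^2))
      expect_lt(abs(sp_grid[i, j] - v_th) / v_th, 0.02)
    }
  }
})

test_that("geostrophic flow is nondivergent at every tested resolution", {
  # spherical divergence (1/(R cos(phi))) [du/dlambda + d(v cos(phi))/dphi]
  # of the constant-f geostrophic flow vanishes identically; with the
  # centred-difference velocities the discrete operators commute, so the
  # residual is zero to rounding at any grid step
  div_max <- vapply(c(1 / 6, 1 / 12), function(dd) {
    grid <- small_grid(d_deg = dd)
    ctr <- c(mean(grid$lon), mean(grid$lat))
    scen <- static_eddy_scenario(ctr, grid = grid)
    uv <- geostrophic_velocity(ssh_field(NULL, scen, grid, 1), grid)
    cosj <- cos(grid$lat * pi / 180)
    dl <- grid$d_deg * pi / 180
    vcos <- sweep(uv$v, 2, cosj, `*`)
    du <- cfeddy:::central_diff(uv$u, 1) / dl
    dvc <- cfeddy:::central_diff(vcos, 2) / dl
    div <- sweep(du + dvc, 2, cfeddy:::EARTH_RADIUS_M * cosj, `/`)
    inner <- div[3:(nrow(div) - 2), 3:(ncol(div) - 2)]
    max(abs(inner))
  }, numeric(1))
  expect_lt(div_max[1], 1e-12)
  expect_lt(div_max[2], 1e-12)
})

test_that("a depression rotates clockwise on the f < 0 plane", {
  st <- make_fixtures("gaussian-eddy")
  grid <- st$grid
  ctr <- c(mean(grid$lon), mean(grid$lat))
  uv <- geostrophic_velocity(st$ssh[, , 1], grid)
  bearings <- seq(0, 350, by = 10)
  circ <- 0
  for (b in bearings) {
    p <- gc_destination(ctr, b, 50e3)
    u <- cfeddy:::interp_bilinear(uv$u, grid$lon, grid$lat, p[1], p[2])
    v <- cfeddy:::interp_bilinear(uv$v, grid$lon, grid$lat, p[1], p[2])
    # anticlockwise tangent at compass bearing b is (-cos b, sin b)
    circ <- circ + (-cos(b * pi / 180)) * u + sin(b * pi / 180) * v
  }
  expect_lt(circ, 0)  # net clockwise circulation
})

test_that("vertical extension decays on the e-folding scale", {
  u_s <- matrix(1, 3, 3); v_s <- matrix(-0.5, 3, 3)
  ext <- extend_velocity_vertical(u_s, v_s, c(0, 100, 500), 500)
  expect_equal(ext$u[1, 1, ], c(1, exp(-0.2), exp(-1)))
  expect_equal(ext$u[1, 1, 2], 0.8187, tolerance = 1e-4)
  expect_true(all(diff(abs(ext$v[2, 2, ])) < 0))
  expect_error(extend_velocity_vertical(u_s, v_s, c(0, 10), -1), "positive")
})

test_that("eddy vertical velocity has core upwelling and trailing-edge downwelling", {
  grid <- small_grid()
  ctr <- c(mean(grid$lon), mean(grid$lat))
  # translating eddy with the default annulus at r = L
  scen <- eddy_scenario(center0 = ctr, L0 = 40, Linf = 40, growth_k = 0,
                        stationary_days = 0, c_slow = 0.1, c_fast = 0.1,
                        w0 = 20, w_up = 5, w_edge_peak = 1,
                        f = grid$f, g = grid$g)
  w <- vertical_velocity(scen, grid, 1)
  ctr1 <- as.vector(eddy_center(scen, 1))  # the centre has drifted by day 1
  k60 <- which.min(abs(grid$depth - 50))
  w_at <- function(p) cfeddy:::interp_bilinear(w[, , k60], grid$lon,
                                               grid$lat, p[1], p[2])
  # upwelling (negative, positive-down convention) at the centre
  expect_lt(w_at(ctr1), 0)
  # far field: |w| < 1e-3 of the edge amplitude
  far <- gc_destination(ctr1, 90, 5 * 40e3)
  expect_lt(abs(w_at(far)), 1e-3 * scen$w0 / 86400)
  # brute-force search over the circle r = L: max downwelling sits at the
  # trailing edge (opposite the propagation heading)
  bearings <- seq(0, 359, by = 3)
  w_ring <- vapply(bearings, function(b) {
    w_at(gc_destination(ctr1, b, 40e3))
  }, numeric(1))
  trailing <- (scen$heading + 180) %% 360
  expect_lt(abs(bearings[which.max(w_ring)] - trailing), 15)
  expect_gt(max(w_ring), 0)  # downwelling is positive (downward)
})

test_that("stationary-phase edge downwelling is azimuthally symmetric", {
  grid <- small_grid()
  ctr <- c(mean(grid$lon), mean(grid$lat))
  scen <- eddy_scenario(center0 = ctr, L0 = 40, Linf = 40, growth_k = 0,
                        stationary_days = 50, c_slow = 0, c_fast = 0,
                        w0 = 20, w_up = 5, w_edge_peak = 1,
                        f = grid$f, g = grid$g)
  w <- vertical_velocity(scen, grid, 1)
  k60 <- which.min(abs(grid$depth - 50))
  w_ring <- vapply(seq(0, 359, by = 10), function(b) {
    p <- gc_destination(ctr, b, 40e3)
    cfeddy:::interp_bilinear(w[, , k60], grid$lon, grid$lat, p[1], p[2])
  }, numeric(1))
  expect_lt(diff(range(w_ring)) / mean(w_ring), 0.05)
})

test_that("temperature spans the water-mass endpoints with eddy doming", {
  grid <- grid_spec()
  # far-field endpoints
  expect_equal(temp_profile(0), 22.9)
  expect_equal(temp_profile(600), 12.9, tolerance = 1e-3)
  expect_true(all(diff(temp_profile(seq(0, 600, 5))) <= 0))
  ctr <- c(-42, -24.2)
  scen <- eddy_scenario(center0 = ctr, L0 = 50, Linf = 50, growth_k = 0,
                        U0 = 1, Uinf = 1, dome_coef = 300,
                        stationary_days = 50, c_slow = 0, c_fast = 0,
                        f = grid$f, g = grid$g)
  tt <- temperature_field(grid, scen, 1)
  # 20 C isotherm depth by root finding, at the centre and far afield
  sch <- eddy_schedule(scen, 1)
  dome_c <- scen$dome_coef * sch$A_m
  z20_far <- uniroot(function(z) temp_profile(z) - 20, c(0, 600))$root
  z20_core <- uniroot(function(z) temp_profile(z + dome_c) - 20,
                      c(-dome_c, 600))$root
  expect_lt(z20_core, z20_far)
  # field values match the profile construction at a node
  i <- which.min(abs(grid$lon - ctr[1])); j <- which.min(abs(grid$lat - ctr[2]))
  expect_lt(tt[i, j, 1], 22.9)
  # bounds hold everywhere
  expect_true(all(tt >= 12.9 - 1e-6 & tt <= 22.9 + 1e-6))
})

test_that("assembled ocean state is finite and geostrophically consistent", {
  grid <- small_grid(t_days = 2)
  bathy <- build_bathymetry(grid)
  jet <- jet_spec()
  scen <- eddy_scenario(center0 = c(mean(grid$lon), mean(grid$lat)),
                        f = grid$f, g = grid$g)
  st <- ocean_state(grid, jet, scen, bathy)
  for (v in c("ssh", "u", "v", "w", "temp")) {
    expect_true(all(is.finite(st[[v]])), info = v)
  }
  uv <- geostrophic_velocity(st$ssh[, , 1], grid)
  expect_equal(st$u[, , 1, 1], uv$u)
  expect_equal(st$v[, , 1, 1], uv$v)
})
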