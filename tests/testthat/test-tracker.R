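test_that("extrema detection finds isolated minima and nothing on flat fields", {
  grid <- small_grid()
  flat <- matrix(0, length(grid$lon), length(grid$lat))
  expect_equal(nrow(find_extrema(flat, grid)), 0)

  ctr <- c(mean(grid$lon), mean(grid$lat))
  scen <- static_eddy_scenario(ctr, grid = grid)
  eta <- ssh_field(NULL, scen, grid, 1)
  ex <- find_extrema(eta, grid)
  expect_equal(nrow(ex), 1)
  # minimum lands on the grid node nearest the analytic centre
  expect_lt(abs(ex$lon - ctr[1]), grid$d_deg)
  expect_lt(abs(ex$lat - ctr[2]), grid$d_deg)

  # two depressions 400 km apart give two minima
  grid2 <- grid_spec(lon_min = -46, lon_max = -38, lat_min = -27,
                     lat_max = -22, t_days = 1, depth_levels = c(0, 100))
  s1 <- static_eddy_scenario(c(-44.5, -24.5), grid = grid2)
  s2 <- static_eddy_scenario(c(-40.5, -24.5), grid = grid2)
  eta2 <- ssh_field(NULL, s1, grid2, 1) + ssh_field(NULL, s2, grid2, 1)
  expect_equal(nrow(find_extrema(eta2, grid2)), 2)
})

test_that("closed contours of a Gaussian depression match the analytic radius", {
  st <- make_fixtures("gaussian-eddy")
  grid <- st$grid
  A <- 0.1; L_km <- 50
  for (lev in c(-0.08, -0.05, -0.02)) {
    cc <- extract_closed_contours(st$ssh[, , 1], grid, lev)
    expect_equal(length(cc), 1)
    r_analytic <- L_km * sqrt(-2 * log(-lev / A))
    geo <- polygon_geometry(cc[[1]]$ring)
    expect_lt(abs(sqrt(geo$area_km2 / pi) - r_analytic), 10)  # ~1 grid step
  }
  # below the extremum: no contour at all
  expect_equal(length(extract_closed_contours(st$ssh[, , 1], grid, -0.12)), 0)
})

test_that("qualification accepts circles and rejects multi-extrema contours", {
  st <- make_fixtures("gaussian-eddy")
  grid <- st$grid
  params <- detection_params()
  ex <- find_extrema(st$ssh[, , 1], grid)
  cc <- extract_closed_contours(st$ssh[, , 1], grid, -0.05)
  q <- qualify(cc[[1]]$ring, -0.05, st$ssh[, , 1], grid, ex, params)
  expect_true(q$ok)
  expect_lt(q$shape_err, 5)

  # superpose two depressions and take a contour surrounding both
  grid2 <- grid_spec(lon_min = -46, lon_max = -38, lat_min = -27,
                     lat_max = -22, t_days = 1, depth_levels = c(0, 100))
  s1 <- static_eddy_scenario(c(-42.8, -24.5), grid = grid2)
  s2 <- static_eddy_scenario(c(-41.2, -24.5), grid = grid2)
  eta2 <- ssh_field(NULL, s1, grid2, 1) + ssh_field(NULL, s2, grid2, 1)
  ex2 <- find_extrema(eta2, grid2)
  expect_equal(nrow(ex2), 2)
  cc2 <- extract_closed_contours(eta2, grid2, -0.02)
  big <- cc2[[which.max(vapply(cc2, function(ct)
    polygon_geometry(ct$ring)$area_km2, numeric(1)))]]
  q2 <- qualify(big$ring, big$level, eta2, grid2, ex2, detection_params())
  expect_false(q2$ok)
  expect_true("multiple extrema" %in% q2$reasons)
})

test_that("assembled observation recovers the analytic Gaussian eddy", {
  st <- make_fixtures("gaussian-eddy")
  grid <- st$grid
  ctr <- c(mean(grid$lon), mean(grid$lat))
  obs <- assemble_eddy(st$ssh[, , 1], grid, detection_params(), t = 1)
  expect_equal(length(obs), 1)
  o <- obs[[1]]
  # swirl speed within 5% of the closed-form maximum 0.205 m/s
  vmax <- (grid$g / abs(grid$f)) * (0.1 / 50e3) * exp(-0.5)
  expect_lt(abs(o$U - vmax) / vmax, 0.05)
  # centroid within one grid step of the analytic centre
  expect_lt(gc_distance(ctr, o$centroid), 1.2 * grid$d_deg * 111.2e3)
  # amplitude within a few contour intervals of A
  expect_lt(abs(o$amplitude - 0.1), 3 * 0.002)
})

test_that("detection recovery holds across eddy amplitudes and scales", {
  grid <- grid_spec(lon_min = -45, lon_max = -39, lat_min = -27,
                    lat_max = -22, t_days = 1, depth_levels = c(0, 100))
  ctr <- c(-42, -24.5)
  for (A in c(0.05, 0.15, 0.3)) {
    for (L in c(30, 50, 70)) {
      scen2 <- eddy_scenario(center0 = ctr, L0 = L, Linf = L, growth_k = 0,
                             U0 = 1, Uinf = 1, stationary_days = 10,
                             c_slow = 0, c_fast = 0, w0 = 0, w_up = 0,
                             dome_coef = 0, f = grid$f, g = grid$g)
      st2 <- ocean_state(grid, NULL, scen2, build_bathymetry(grid))
      st2 <- pin_amplitude(st2, A)
      obs <- assemble_eddy(st2$ssh[, , 1], grid, detection_params(), 1)
      expect_equal(length(obs), 1, info = sprintf("A=%g L=%g", A, L))
      o <- obs[[1]]
      expect_lt(gc_distance(ctr, o$centroid), grid$d_deg * 111.5e3)
      vmax <- (grid$g / abs(grid$f)) * (A / (L * 1000)) * exp(-0.5)
      expect_lt(abs(o$U - vmax) / vmax, 0.05,
                label = sprintf("U error A=%g L=%g", A, L))
    }
  }
})

test_that("tracking follows displaced eddies and terminates across gaps", {
  mk_obs <- function(day, lon, lat, r = 40, amp = 0.1) {
    structure(list(t = day, centroid = c(lon, lat), amplitude = amp,
                   radius_km = r, contour = NULL, U = 0.5, shape_err = 5,
                   n_pixels = 50, level = -0.05), class = "eddy_observation")
  }
  # single eddy drifting 5 km/day: one unbroken track
  days <- lapply(1:30, function(d) {
    p <- gc_destination(c(-42, -24), 225, 5000 * (d - 1))
    list(mk_obs(d, p[1], p[2]))
  })
  tr <- track_eddies(days)
  expect_equal(length(tr), 1)
  expect_equal(nrow(tr[[1]]$obs), 30)
  expect_equal(mean(tr[[1]]$obs$c_ms, na.rm = TRUE), 5000 / 86400,
               tolerance = 1e-3)
  # a missing day terminates the track (no gap bridging)
  days_gap <- days
  days_gap[[10]] <- list()
  tr_gap <- track_eddies(days_gap)
  expect_equal(sort(vapply(tr_gap, function(t) nrow(t$obs), numeric(1))),
               c(9, 20))
})

test_that("two crossing eddies keep their identities", {
  st <- make_fixtures("crossing-eddies", t_days = 10)
  det <- detect_eddies(st)
  expect_true(all(vapply(det, length, numeric(1)) == 2))
  tr <- track_eddies(det)
  expect_equal(length(tr), 2)
  for (t in tr) expect_equal(nrow(t$obs), 10)
  # compare with the generator's ground-truth lanes: a track stays in its lane
  lats <- vapply(tr, function(t) mean(t$obs$lat), numeric(1))
  expect_equal(sort(round(lats, 1)), c(-25.2, -24.0), tolerance = 0.05)
  # permuting the per-day candidate order never changes the result
  det_perm <- lapply(det, rev)
  tr2 <- track_eddies(det_perm)
  expect_equal(sort(vapply(tr2, function(t) mean(t$obs$lat), numeric(1))),
               sort(lats))
})

test_that("nonlinearity handles plain ratios and all-zero translation", {
  mk <- function(U, c_ms) {
    structure(list(obs = data.frame(day = seq_along(U), U = U, c_ms = c_ms)),
              class = "eddy_track")
  }
  nl <- nonlinearity(mk(c(0.5, 0.5), c(NA, 0.1)))
  expect_equal(nl$series$U_over_c, 5)
  nl0 <- nonlinearity(mk(c(0.5, 0.5), c(NA, 0)))
  expect_true(nl0$all_zero_c)
  expect_equal(nl0$n_zero_c, 1)
})

test_that("growth fit recovers logistic rates and flags degenerate input", {
  t <- 1:30
  r_true <- 31.9 * 72.6 * exp(0.052 * (t - 1)) /
    (72.6 + 31.9 * (exp(0.052 * (t - 1)) - 1))
  fit <- fit_growth(t, r_true)
  expect_equal(fit$k, 0.052, tolerance = 5e-4)
  expect_gt(fit$r_squared, 0.9999)
  fit_const <- fit_growth(1:10, rep(40, 10))
  expect_equal(fit_const$k, 0)
  expect_equal(fit_const$plateau_day, 1)
  expect_error(fit_growth(1:4, c(1, 2, 3, 4)), "at least 5")
})
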