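# a minimal hand-built trajectory_set: positions per day for n larvae
fake_traj <- function(lon, lat, z, release_day, exit_day = NULL, sched = NULL) {
  n <- nrow(lon)
  structure(list(
    lon = lon, lat = lat, z = z,
    release_day = release_day,
    exit_day = if (is.null(exit_day)) rep(NA_integer_, n) else exit_day,
    status = if (is.null(exit_day)) rep("active", n)
             else ifelse(is.na(exit_day), "active", "exited"),
    n = n, t_days = ncol(lon),
    sched = if (is.null(sched)) list(center = c(-41.255, -23.316)) else sched,
    mix = NULL, seed = 1, scale = 1), class = "trajectory_set")
}

# a track with one circular contour per day around a fixed centre
fake_track <- function(ctr, radius_km, days = 1:3) {
  th <- seq(0, 359, by = 5)
  contours <- lapply(days, function(d) gc_destination(ctr, th, radius_km * 1000))
  structure(list(obs = data.frame(day = days, lon = ctr[1], lat = ctr[2],
                                  amplitude = 0.1, radius_km = radius_km,
                                  U = 0.5, shape_err = 2, n_pixels = 50,
                                  c_ms = 0.05, cumulative_km = 0),
                 contours = contours), class = "eddy_track")
}

test_that("capture classification uses in-domain denominators and flags gaps", {
  ctr <- c(-42, -24)
  track <- fake_track(ctr, 30, days = c(1, 3))  # no observation on day 2
  inside_pt <- gc_destination(ctr, 90, 10e3)
  outside_pt <- gc_destination(ctr, 90, 100e3)
  lon <- rbind(c(inside_pt[1], inside_pt[1], inside_pt[1]),
               c(outside_pt[1], outside_pt[1], inside_pt[1]))
  lat <- rbind(c(inside_pt[2], inside_pt[2], inside_pt[2]),
               c(outside_pt[2], outside_pt[2], inside_pt[2]))
  tr <- fake_traj(lon, lat, lon * 0, c(1L, 1L))
  cap <- capture_series(tr, track)
  expect_equal(cap$trapped_pct[1], 50)
  expect_true(is.na(cap$trapped_pct[2]))       # gap day
  expect_equal(cap$trapped_pct[3], 100)
  expect_equal(cap$days_inside, c(2, 1))
  # inside + outside = 100 on defined days
  ok <- !is.na(cap$trapped_pct)
  expect_equal(cap$trapped_pct[ok] + cap$outside_pct[ok], rep(100, sum(ok)))
})

test_that("all larvae seeded inside a contour are captured on day one", {
  ctr <- c(-42, -24)
  track <- fake_track(ctr, 50, days = 1)
  set.seed(51)
  pts <- gc_destination(ctr, runif(40, 0, 360), runif(40, 0, 40e3))
  tr <- fake_traj(matrix(pts[, 1], 40, 1), matrix(pts[, 2], 40, 1),
                  matrix(0, 40, 1), rep(1L, 40))
  cap <- capture_series(tr, track)
  expect_equal(cap$trapped_pct[1], 100)
})

test_that("origin distances follow spherical trigonometry with exit freezing", {
  origin <- c(-41.255, -23.316)
  south1 <- c(origin[1], origin[2] - 1)
  lon <- rbind(c(origin[1], origin[1]), c(south1[1], south1[1]))
  lat <- rbind(c(origin[2], origin[2]), c(south1[2], south1[2]))
  tr <- fake_traj(lon, lat, lon * 0, c(1L, 1L))
  d <- origin_distance(tr)
  expect_equal(d[1], 0)
  expect_equal(d[2], 111.2, tolerance = 0.001)  # 1 degree due south
  # an exited larva keeps its last recorded position in later records,
  # so its distance never changes after the exit day
  tr2 <- fake_traj(lon, lat, lon * 0, c(1L, 1L), exit_day = c(NA, 1L))
  expect_equal(origin_distance(tr2)[2], origin_distance(tr2, day = 1)[2])
})

test_that("residence-distance correlation is exact, bounded and null-safe", {
  expect_equal(residence_distance_correlation(c(0, 10, 20, 30),
                                              c(600, 400, 200, 0)), -1)
  # affine rescaling leaves r unchanged
  expect_equal(residence_distance_correlation(c(0, 10, 20, 30) * 3 + 2,
                                              c(600, 400, 200, 0)), -1)
  set.seed(52)
  x <- sample(0:30, 1e4, replace = TRUE)
  y <- sample(seq(0, 800, 10), 1e4, replace = TRUE)
  expect_lt(abs(residence_distance_correlation(x, y)), 0.05)
  expect_error(residence_distance_correlation(rep(3, 10), runif(10)),
               "constant")
  expect_error(residence_distance_correlation(1:2, 1:2), "at least 3")
})

test_that("depth statistics pool larva-day records with exact counting", {
  z <- rbind(rep(0, 4), rep(100, 4))
  lon <- matrix(-42, 2, 4); lat <- matrix(-24, 2, 4)
  tr <- fake_traj(lon, lat, z, c(1L, 1L))
  ds <- depth_statistics(tr)
  expect_equal(ds$deep_fraction_pct, 50)
  expect_equal(ds$n_records, 8)
  expect_equal(sum(ds$histogram), 8)
  tr_surface <- fake_traj(lon, lat, z * 0, c(1L, 1L))
  expect_equal(depth_statistics(tr_surface)$deep_fraction_pct, 0)
})

test_that("vicinity classification distinguishes near and far deep larvae", {
  ctr <- c(-42, -24)
  track <- fake_track(ctr, 40, days = 1)
  near <- gc_destination(ctr, 0, 20e3)
  far <- gc_destination(ctr, 0, 400e3)
  lon <- matrix(c(near[1], far[1], near[1]), 3, 1)
  lat <- matrix(c(near[2], far[2], near[2]), 3, 1)
  z <- matrix(c(80, 90, 10), 3, 1)  # two deep, one shallow
  tr <- fake_traj(lon, lat, z, rep(1L, 3))
  v <- vicinity_fraction(tr, track, 1)
  expect_equal(v$n_deep, 2)
  expect_equal(v$pct, 50)
  # no deep larvae: undefined, flagged
  v0 <- vicinity_fraction(fake_traj(lon, lat, z * 0, rep(1L, 3)), track, 1)
  expect_true(is.na(v0$pct) && v0$n_deep == 0)
})

test_that("cold exposure matches a direct profile lookup", {
  grid <- small_grid()
  st <- still_state(grid)
  # far-field stratification in the temp array
  for (k in seq_along(grid$depth)) st$temp[, , k, 1] <- temp_profile(grid$depth[k])
  z20 <- uniroot(function(z) temp_profile(z) - 20, c(0, 600))$root
  lon <- matrix(-42, 2, 1); lat <- matrix(-24, 2, 1)
  z <- matrix(c(0, min(z20 + 10, 100)), 2, 1)
  tr <- fake_traj(lon, lat, z, c(1L, 1L))
  ce <- cold_exposure(tr, st, 1)
  expect_equal(ce$n, 2)
  expect_equal(ce$pct, 50)  # only the sub-thermocline larva is cold
  surface_only <- fake_traj(lon, lat, z * 0, c(1L, 1L))
  expect_equal(cold_exposure(surface_only, st, 1)$pct, 0)
})

test_that("coastal arrivals are counted once per larva by bathymetry lookup", {
  grid <- small_grid()
  st <- still_state(grid)
  st$bathy_h[] <- 1000
  st$bathy_h[1:10, ] <- 100  # a shallow strip on the western edge
  shallow_lon <- grid$lon[5]; deep_lon <- grid$lon[30]
  lon <- rbind(c(deep_lon, shallow_lon, shallow_lon), rep(deep_lon, 3))
  lat <- matrix(-24, 2, 3)
  tr <- fake_traj(lon, lat, lon * 0, c(1L, 1L))
  ca <- coastal_arrivals(tr, st)
  expect_equal(ca$count, 1)
  expect_equal(ca$ids, 1)
})

test_that("density map conserves larva-day records", {
  grid <- small_grid()
  lon <- matrix(grid$lon[10], 1, 30)
  lat <- matrix(grid$lat[10], 1, 30)
  tr <- fake_traj(lon, lat, lon * 0, 1L)
  dm <- density_map(tr, grid)
  expect_equal(max(dm), 30)
  expect_equal(sum(dm), 30)
  expect_equal(sum(dm > 0), 1)
})
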