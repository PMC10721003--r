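#' Reference scenario configuration
#'
#' The parameter set encoding the study conditions: the boundary-jet and
#' cyclonic-eddy schedules, the 16-day x 3000-larvae release, mixing,
#' detection and analysis parameters. Shipped as a plain-text YAML file;
#' every value can be overridden by editing a copy.
#'
#' @param path YAML file to read; `NULL` loads the packaged reference file.
#' @return A validated config list (class `scenario_config`).
#' @export
load_scenario_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_scenario.yaml",
                        package = "cfeddy")
  }
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a scenario configuration
#'
#' Checks every block against the module invariants before any compute;
#' returns the config with class `scenario_config` and defaults filled in.
#'
#' @param cfg A config list (blocks `grid`, `bathy`, `jet`, `eddy`,
#'   `release`, `mixing`, `detection`, `analysis`, `run`).
#' @return The validated config.
#' @export
validate_config <- function(cfg) {
  # constructors carry the invariant checks; build everything once
  grid <- do.call(grid_spec, cfg$grid %||% list())
  do.call(build_bathymetry, c(list(grid = grid), cfg$bathy %||% list()))
  do.call(jet_spec, cfg$jet %||% list())
  eddy_args <- cfg$eddy %||% list()
  eddy_args$center0 <- unlist(eddy_args$center0 %||% c(-42.0, -24.2))
  eddy_args$f <- grid$f; eddy_args$g <- grid$g
  do.call(eddy_scenario, eddy_args)
  rel_args <- cfg$release %||% list()
  if (!is.null(rel_args$center)) rel_args$center <- unlist(rel_args$center)
  do.call(release_schedule, rel_args)
  do.call(mixing_spec, cfg$mixing %||% list())
  do.call(detection_params, cfg$detection %||% list())
  an <- cfg$analysis %||% list()
  cfg$analysis <- utils::modifyList(
    list(depth_threshold_m = 60, temp_threshold_c = 20,
         vicinity_factor = 1.5, vicinity_day = 15, cold_day = 26,
         capture_day = 10, outside_day = 16, isobath_m = 200), an)
  cfg$run <- utils::modifyList(list(scale = 1, seed = 1), cfg$run %||% list())
  structure(cfg, class = c("scenario_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full scenario pipeline
#'
#' Generator -> eddy tracker -> Lagrangian floats -> dispersal analysis,
#' returning a results bundle whose summary carries every headline
#' statistic with its definition. Deterministic given `seed`.
#'
#' @param cfg A `scenario_config` (default: the packaged reference).
#' @param seed RNG seed; overrides the config.
#' @param scale Release scale factor; overrides the config.
#' @param outdir If non-NULL, write the bundle files (NetCDF fields,
#'   trajectory CSV, track CSV/JSON, contour GeoJSON, summary JSON) there.
#' @param write_fields_file Also write the (large) NetCDF fields file when
#'   `outdir` is given.
#' @param verbose Log stage progress.
#' @return List of class `results_bundle`: `config`, `config_hash`,
#'   `state`, `detections`, `track`, `growth`, `nonlin`, `traj`, `capture`,
#'   `summary`.
#' @export
run_scenario <- function(cfg = load_scenario_config(), seed = NULL,
                         scale = NULL, outdir = NULL,
                         write_fields_file = FALSE, verbose = FALSE) {
  cfg <- validate_config(cfg)
  if (!is.null(seed)) cfg$run$seed <- seed
  if (!is.null(scale)) cfg$run$scale <- scale
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/4: synthetic ocean fields")
  grid <- do.call(grid_spec, cfg$grid %||% list())
  bathy <- do.call(build_bathymetry, c(list(grid = grid), cfg$bathy %||% list()))
  jet <- do.call(jet_spec, cfg$jet %||% list())
  eddy_args <- cfg$eddy %||% list()
  eddy_args$center0 <- unlist(eddy_args$center0 %||% c(-42.0, -24.2))
  eddy_args$f <- grid$f; eddy_args$g <- grid$g
  scen <- do.call(eddy_scenario, eddy_args)
  state <- ocean_state(grid, jet, scen, bathy)

  say("stage 2/4: eddy identification and tracking")
  params <- do.call(detection_params, cfg$detection %||% list())
  detections <- detect_eddies(state, params)
  tracks <- track_eddies(detections)
  if (!length(tracks)) stop("tracker stage: no eddy track found")
  track <- tracks[[1]]
  growth <- fit_growth(track$obs$day, track$obs$radius_km)
  nonlin <- nonlinearity(track)

  say("stage 3/4: Lagrangian floats (scale %.2f, seed %d)",
      cfg$run$scale, cfg$run$seed)
  rel_args <- cfg$release %||% list()
  if (!is.null(rel_args$center)) rel_args$center <- unlist(rel_args$center)
  sched <- do.call(release_schedule, rel_args)
  mix <- do.call(mixing_spec, cfg$mixing %||% list())
  traj <- run_simulation(state, sched, mix, seed = cfg$run$seed,
                         scale = cfg$run$scale, verbose = verbose)

  say("stage 4/4: dispersal statistics")
  an <- cfg$analysis
  capture <- capture_series(traj, track)
  dist_km <- origin_distance(traj)
  r <- residence_distance_correlation(capture$days_inside, dist_km)
  depth <- depth_statistics(traj, an$depth_threshold_m)
  vic <- vicinity_fraction(traj, track, an$vicinity_day,
                           an$depth_threshold_m, an$vicinity_factor)
  vic_sens <- vapply(c(1.25, 1.5, 2.0), function(fc) {
    vicinity_fraction(traj, track, an$vicinity_day,
                      an$depth_threshold_m, fc)$pct
  }, numeric(1))
  cold <- cold_exposure(traj, state, an$cold_day, an$temp_threshold_c)
  coast <- coastal_arrivals(traj, state, an$isobath_m)
  dens <- density_map(traj, grid)

  def <- function(value, definition, module) {
    list(value = value, definition = definition, module = module)
  }
  summary <- list(
    released_total = def(traj$n, "larvae released over the planulation event",
                         "lagrangian_floats::release"),
    trapped_pct_day10 = def(capture$trapped_pct[an$capture_day],
      "percent of in-domain larvae inside the effective contour, day 10",
      "dispersal_analysis::capture_series"),
    trapped_pct_day30 = def(capture$trapped_pct[traj$t_days],
      "percent of in-domain larvae inside the effective contour, final day",
      "dispersal_analysis::capture_series"),
    outside_pct_day16 = def(100 - capture$trapped_pct[an$outside_day],
      "percent of in-domain larvae outside the eddy, last release day",
      "dispersal_analysis::capture_series"),
    pearson_r = def(r,
      "Pearson correlation of per-larva days inside the eddy vs origin distance at day 30",
      "dispersal_analysis::residence_distance_correlation"),
    deep_fraction_pct = def(depth$deep_fraction_pct,
      "percent of larva-day records deeper than the depth threshold",
      "dispersal_analysis::depth_statistics"),
    vicinity_pct = def(vic$pct,
      "percent of deep larvae within the eddy vicinity on the analysis day",
      "dispersal_analysis::vicinity_fraction"),
    vicinity_sensitivity = def(stats::setNames(vic_sens, c("1.25", "1.5", "2")),
      "vicinity percentage for factors 1.25/1.5/2.0 of the effective radius",
      "dispersal_analysis::vicinity_fraction"),
    cold_pct = def(cold$pct,
      "percent of in-domain larvae in water colder than the threshold on the analysis day",
      "dispersal_analysis::cold_exposure"),
    coastal_arrivals = def(coast$count,
      "larvae ever recorded shoreward of the barrier isobath",
      "dispersal_analysis::coastal_arrivals"),
    max_origin_km = def(max(dist_km, na.rm = TRUE),
      "maximum per-larva distance from the release origin at day 30",
      "dispersal_analysis::origin_distance"),
    mean_radius_km = def(mean(track$obs$radius_km),
      "mean tracked effective radius over the 30-day track",
      "eddy_tracker::assemble_eddy"),
    mean_U = def(mean(track$obs$U),
      "mean swirl speed over the track", "eddy_tracker::assemble_eddy"),
    mean_c = def(mean(track$obs$c_ms, na.rm = TRUE),
      "mean translation speed over the track", "eddy_tracker::track"),
    mean_U_over_c = def(nonlin$summary[["mean"]],
      "mean nonlinearity ratio over days with nonzero translation",
      "eddy_tracker::nonlinearity"),
    growth_k = def(growth$k,
      "logistic growth rate fitted to the tracked radius series",
      "eddy_tracker::fit_growth"),
    growth_r_squared = def(growth$r_squared,
      "r-squared of the radius growth fit", "eddy_tracker::fit_growth"))

  bundle <- structure(
    list(config = cfg, config_hash = config_hash(cfg), state = state,
         detections = detections, track = track, growth = growth,
         nonlin = nonlin, traj = traj, capture = capture,
         origin_km = dist_km, density = dens, summary = summary),
    class = "results_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir, write_fields_file)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>", x$config_hash, "\n")
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]$value
    if (length(v) == 1 && is.numeric(v)) {
      cat(sprintf("  %-20s %.4g\n", nm, v))
    }
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' @param bundle A `results_bundle`.
#' @param outdir Output directory (created if needed).
#' @param write_fields_file Also write the NetCDF fields (large).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir, write_fields_file = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (write_fields_file) {
    write_fields(bundle$state, file.path(outdir, "fields.nc"))
  }
  write_trajectories(bundle$traj, file.path(outdir, "trajectories.csv"))
  utils::write.csv(bundle$track$obs, file.path(outdir, "track.csv"),
                   row.names = FALSE)
  write_contours_geojson(bundle$track, file.path(outdir, "contours.geojson"))
  summ <- lapply(bundle$summary, function(s) {
    s$value <- unname(s$value); s
  })
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, summary = summ,
         track_stats = track_table(bundle$track, bundle$nonlin)),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

# mean/sd/min/max table for radius, c, U, U/c (the tracked-eddy metrics)
track_table <- function(track, nonlin = nonlinearity(track)) {
  stat <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
  }
  list(radius_km = stat(track$obs$radius_km),
       c_ms = stat(track$obs$c_ms),
       U_ms = stat(track$obs$U),
       U_over_c = stat(nonlin$series$U_over_c))
}

#' Write per-day effective contours as GeoJSON
#'
#' One polygon feature per tracked day, with amplitude, radius and swirl
#' speed as properties.
#'
#' @param track An `eddy_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(track, path) {
  feats <- lapply(seq_len(nrow(track$obs)), function(i) {
    ring <- close_ring(track$contours[[i]])
    list(type = "Feature",
         properties = list(day = track$obs$day[i],
                           amplitude_m = track$obs$amplitude[i],
                           radius_km = track$obs$radius_km[i],
                           U_ms = track$obs$U[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(k) unname(ring[k, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analytic test fixtures
#'
#' Small gridded inputs with known ground truth, generated in code:
#' \describe{
#'   \item{`gaussian-eddy`}{A stationary, growth-free Gaussian SSH
#'     depression (no jet), default A = 0.1 m, L = 50 km, on a 1/12-degree
#'     grid; the azimuthal speed closed form is
#'     `(g/|f|) (r/L^2) A exp(-r^2/(2 L^2))`.}
#'   \item{`solid-body`}{A velocity field that is solid-body rotation in
#'     grid coordinates with angular rate `omega` (rad/s): closed circular
#'     orbits with period `2 pi / omega`.}
#'   \item{`crossing-eddies`}{An SSH series with two depressions on
#'     straight crossing tracks (ground-truth association known).}
#' }
#'
#' @param kind Fixture name.
#' @param A,L_km Gaussian eddy amplitude (m) and scale (km).
#' @param omega Solid-body angular rate, rad/s.
#' @param t_days Days in the series (crossing-eddies).
#' @param grid Optional [grid_spec()] override.
#' @return An `ocean_state` (fields not needed by the fixture are zero).
#' @export
make_fixtures <- function(kind, A = 0.1, L_km = 50, omega = 2 * pi / 43200,
                          t_days = 10, grid = NULL) {
  switch(kind,
    "gaussian-eddy" = {
      if (is.null(grid)) {
        grid <- grid_spec(lon_min = -44, lon_max = -40, lat_min = -26,
                          lat_max = -22.5, t_days = 1,
                          depth_levels = c(0, 50, 100))
      }
      scen <- eddy_scenario(center0 = c(mean(grid$lon), mean(grid$lat)),
                            L0 = L_km, Linf = L_km, growth_k = 0,
                            U0 = 1, Uinf = 1, stationary_days = grid$t_days,
                            c_slow = 0, c_fast = 0,
                            w0 = 0, w_up = 0, dome_coef = 0,
                            f = grid$f, g = grid$g)
      # pin the amplitude exactly (the schedule otherwise slaves A to U)
      state <- ocean_state(grid, NULL, scen)
      for (i in seq_along(state$days)) {
        sch <- eddy_schedule(scen, state$days[i])
        state$ssh[, , i] <- state$ssh[, , i] * (A / sch$A_m)
        uv <- geostrophic_velocity(state$ssh[, , i], grid)
        uv3 <- extend_velocity_vertical(uv$u, uv$v, grid$depth, 500)
        state$u[, , , i] <- uv3$u
        state$v[, , , i] <- uv3$v
      }
      state$scen <- scen
      state
    },
    "solid-body" = {
      if (is.null(grid)) {
        grid <- grid_spec(lon_min = -43.5, lon_max = -41.5, lat_min = -25,
                          lat_max = -23.4, t_days = 2,
                          depth_levels = c(0, 100))
      }
      lon0 <- mean(grid$lon); lat0 <- mean(grid$lat)
      nx <- length(grid$lon); ny <- length(grid$lat)
      nz <- length(grid$depth); nt <- grid$t_days
      lonm <- matrix(grid$lon, nx, ny)
      latm <- matrix(grid$lat, nx, ny, byrow = TRUE)
      # clockwise solid-body rotation in grid coordinates:
      # dlon/dt = omega (lat - lat0), dlat/dt = -omega (lon - lon0)
      u2 <- omega * (latm - lat0) * m_per_deg_lon(latm)
      v2 <- -omega * (lonm - lon0) * m_per_deg_lat(latm)
      u <- array(rep(u2, nz * nt), c(nx, ny, nz, nt))
      v <- array(rep(v2, nz * nt), c(nx, ny, nz, nt))
      structure(list(grid = grid, days = seq_len(nt),
                     ssh = array(0, c(nx, ny, nt)), u = u, v = v,
                     w = array(0, c(nx, ny, nz, nt)),
                     temp = array(20, c(nx, ny, nz, nt)),
                     bathy_h = matrix(1000, nx, ny),
                     bathy = NULL, jet = NULL, scen = NULL,
                     omega = omega, center = c(lon0, lat0)),
                class = "ocean_state")
    },
    "crossing-eddies" = {
      if (is.null(grid)) {
        grid <- grid_spec(lon_min = -46, lon_max = -38, lat_min = -27,
                          lat_max = -22, t_days = t_days,
                          depth_levels = c(0, 100))
      }
      nx <- length(grid$lon); ny <- length(grid$lat)
      ssh <- array(0, c(nx, ny, grid$t_days))
      truth <- list(a = matrix(NA, grid$t_days, 2),
                    b = matrix(NA, grid$t_days, 2))
      for (d in seq_len(grid$t_days)) {
        frac <- (d - 1) / max(1, grid$t_days - 1)
        ca <- c(-45 + 6 * frac, -24.0)        # eastbound, north lane
        cb <- c(-39 - 6 * frac, -25.2)        # westbound, south lane
        truth$a[d, ] <- ca; truth$b[d, ] <- cb
        da <- gc_dist_grid(grid, ca); db <- gc_dist_grid(grid, cb)
        ssh[, , d] <- -A * exp(-da^2 / (2 * (L_km * 1000)^2)) -
          A * exp(-db^2 / (2 * (L_km * 1000)^2))
      }
      structure(list(grid = grid, days = seq_len(grid$t_days), ssh = ssh,
                     u = NULL, v = NULL, w = NULL, temp = NULL,
                     bathy_h = matrix(3000, nx, ny), bathy = NULL,
                     jet = NULL, scen = NULL, truth = truth),
                class = "ocean_state")
    },
    stop("unknown fixture kind: ", kind))
}
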