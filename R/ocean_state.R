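#' Assemble the full synthetic ocean state
#'
#' Evaluates SSH, surface-geostrophic velocities extended down the column,
#' vertical velocity and temperature on every daily snapshot, plus the
#' static bathymetry. This is the gridded stand-in for a primitive-equation
#' hindcast: kinematically consistent (velocities are exactly geostrophic
#' with respect to SSH at the surface) but analytically controlled.
#'
#' @param grid A [grid_spec()].
#' @param jet A [jet_spec()] or `NULL`.
#' @param scen An [eddy_scenario()] or `NULL`.
#' @param bathy A [build_bathymetry()]; built with defaults if `NULL`.
#' @param days Integer vector of snapshot days (default `1:grid$t_days`).
#' @return Object of class `ocean_state`: arrays `ssh` (lon x lat x day),
#'   `u`, `v`, `w`, `temp` (lon x lat x depth x day), matrix `bathy_h`,
#'   plus `grid`, `days` and the input specs.
#' @export
ocean_state <- function(grid, jet, scen, bathy = NULL,
                        days = seq_len(grid$t_days)) {
  if (is.null(bathy)) bathy <- build_bathymetry(grid)
  nx <- length(grid$lon); ny <- length(grid$lat)
  nz <- length(grid$depth); nt <- length(days)
  ssh <- array(NA_real_, c(nx, ny, nt))
  u <- array(NA_real_, c(nx, ny, nz, nt)); v <- u; w <- u; temp <- u
  vert_scale <- if (!is.null(jet)) jet$vert_scale else 500
  for (i in seq_len(nt)) {
    t <- days[i]
    eta <- ssh_field(jet, scen, grid, t, bathy)
    ssh[, , i] <- eta
    uv <- geostrophic_velocity(eta, grid)
    uv3 <- extend_velocity_vertical(uv$u, uv$v, grid$depth, vert_scale)
    u[, , , i] <- uv3$u
    v[, , , i] <- uv3$v
    w[, , , i] <- if (!is.null(scen)) vertical_velocity(scen, grid, t) else 0
    temp[, , , i] <- temperature_field(grid, scen, t)
  }
  structure(list(grid = grid, days = days, ssh = ssh, u = u, v = v,
                 w = w, temp = temp, bathy_h = bathy$h, bathy = bathy,
                 jet = jet, scen = scen),
            class = "ocean_state")
}

#' @export
print.ocean_state <- function(x, ...) {
  cat(sprintf("<ocean_state> %d days, grid %d x %d x %d\n",
              length(x$days), length(x$grid$lon), length(x$grid$lat),
              length(x$grid$depth)))
  invisible(x)
}

#' Write an ocean state to a CF-style NetCDF file
#'
#' Variables `ssh(time, lat, lon)`, `u/v/w/temp(time, depth, lat, lon)` and
#' `bathy(lat, lon)` with units attributes; time in days, longitude in
#' degrees_east, latitude in degrees_north, depth in metres positive down.
#'
#' @param state An [ocean_state()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fields <- function(state, path) {
  g <- state$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  ddep <- ncdf4::ncdim_def("depth", "m", g$depth)
  dtim <- ncdf4::ncdim_def("time", "days since start", as.double(state$days),
                           unlim = TRUE)
  d2 <- list(dlon, dlat)
  d3 <- list(dlon, dlat, dtim)
  d4 <- list(dlon, dlat, ddep, dtim)
  vars <- list(
    ncdf4::ncvar_def("ssh", "m", d3, missval = NA_real_, prec = "double"),
    ncdf4::ncvar_def("u", "m s-1", d4, missval = NA_real_, prec = "double"),
    ncdf4::ncvar_def("v", "m s-1", d4, missval = NA_real_, prec = "double"),
    ncdf4::ncvar_def("w", "m s-1", d4, missval = NA_real_, prec = "double",
                     longname = "vertical velocity, positive down"),
    ncdf4::ncvar_def("temp", "degC", d4, missval = NA_real_, prec = "double"),
    ncdf4::ncvar_def("bathy", "m", d2, missval = NA_real_, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, "ssh", state$ssh)
  ncdf4::ncvar_put(nc, "u", state$u)
  ncdf4::ncvar_put(nc, "v", state$v)
  ncdf4::ncvar_put(nc, "w", state$w)
  ncdf4::ncvar_put(nc, "temp", state$temp)
  ncdf4::ncvar_put(nc, "bathy", state$bathy_h)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8 (style)")
  ncdf4::ncatt_put(nc, 0, "positive_down",
                   "depth and w are positive downward")
  invisible(path)
}

#' Read an ocean state from a NetCDF file written by [write_fields()]
#'
#' Validates that all variables are present and that the axes are strictly
#' monotone; rejects files with permuted dimension order.
#'
#' @param path NetCDF file path.
#' @return An `ocean_state` (without jet/eddy specs, which are not stored).
#' @export
read_fields <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  need <- c("ssh", "u", "v", "w", "temp", "bathy")
  missing <- setdiff(need, names(nc$var))
  if (length(missing)) {
    stop("file is missing variable(s): ", paste(missing, collapse = ", "))
  }
  lon <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  depth <- as.vector(ncdf4::ncvar_get(nc, "depth"))
  days <- as.vector(ncdf4::ncvar_get(nc, "time"))
  for (ax in list(lon = lon, lat = lat, depth = depth, time = days)) {
    if (any(diff(ax) <= 0)) stop("non-monotone axis in file")
  }
  expect_dims <- c("lon", "lat", "depth", "time")
  got <- vapply(nc$var[["u"]]$dim, function(d) d$name, character(1))
  if (!identical(got, expect_dims)) {
    stop("unexpected dimension order for 'u': ", paste(got, collapse = ","),
         " (expected ", paste(expect_dims, collapse = ","), ")")
  }
  grid <- grid_spec(lon_min = min(lon), lon_max = max(lon),
                    lat_min = min(lat), lat_max = max(lat),
                    d_deg = diff(lon[1:2]), depth_levels = depth,
                    t_days = length(days))
  grid$lon <- lon; grid$lat <- lat
  structure(list(grid = grid, days = as.numeric(days),
                 ssh = array(ncdf4::ncvar_get(nc, "ssh", collapse_degen = FALSE),
                             c(length(lon), length(lat), length(days))),
                 u = ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE),
                 v = ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE),
                 w = ncdf4::ncvar_get(nc, "w", collapse_degen = FALSE),
                 temp = ncdf4::ncvar_get(nc, "temp", collapse_degen = FALSE),
                 bathy_h = ncdf4::ncvar_get(nc, "bathy"),
                 bathy = NULL, jet = NULL, scen = NULL),
            class = "ocean_state")
}
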