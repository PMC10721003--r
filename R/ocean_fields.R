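#' Sea-surface height field for one day
#'
#' Total SSH is the sum of a jet component and an eddy component. The jet
#' component is a cross-stream integrated Gaussian (an offshore rise of
#' SSH whose geostrophic shear is the south-westward jet, with the coastal
#' set-down that supports it); the eddy component is a Gaussian depression
#' `-A(t) exp(-d^2 / (2 L(t)^2))` about the scheduled centre, `d` being the
#' (optionally elliptical, see [eddy_metric()]) distance to the centre,
#' with an optional opposing outer ring for shielded-vortex experiments.
#'
#' @param jet A [jet_spec()]; pass `NULL` for an eddy-only field.
#' @param scen An [eddy_scenario()]; pass `NULL` for a jet-only field.
#' @param grid A [grid_spec()].
#' @param t Day.
#' @param bathy A [build_bathymetry()] for the jet axis geometry (required
#'   when `jet` is given).
#' @return SSH matrix in metres, dims lon x lat.
#' @export
ssh_field <- function(jet, scen, grid, t, bathy = NULL) {
  if (t < 0 || t > grid$t_days) stop("day t out of range")
  eta <- matrix(0, length(grid$lon), length(grid$lat))
  if (!is.null(jet)) {
    if (is.null(bathy)) stop("jet SSH needs the bathymetry for its axis")
    eta <- eta + jet_ssh(jet, grid, bathy)
  }
  if (!is.null(scen)) {
    sch <- eddy_schedule(scen, t)
    em <- eddy_metric_grid(scen, grid, t)
    x2 <- (em$d_eff_m / (sch$L_km * 1000))^2
    shape <- exp(-x2 / 2)
    if (scen$shield_amp > 0) {
      shape <- shape - scen$shield_amp * exp(-x2 / (2 * scen$shield_width^2))
    }
    eta <- eta - sch$A_m * shape
  }
  eta
}

# jet SSH component (time-invariant): eta = drop * (Phi(s/W) - 1), s the
# signed coast distance minus the axis standoff; 0 far offshore, -drop at
# the coast. Geostrophic shear across it is a Gaussian jet of the configured
# core speed.
jet_ssh <- function(jet, grid, bathy) {
  d_axis <- isobath_distance_km(bathy, jet$axis_isobath_m)
  s_m <- (bathy$coast_dist - d_axis) * 1000
  w_m <- jet$cross_width * 1000
  if (jet$widen_factor > 1) {
    # seaward-only broadening: the inshore flank keeps its width so the
    # slowing current fans offshore, never toward the coast
    lonm <- matrix(grid$lon, length(grid$lon), length(grid$lat))
    widen <- 1 + (jet$widen_factor - 1) *
      stats::pnorm((jet$taper_lon - lonm) / 1.5)
    w_m <- ifelse(s_m > 0, w_m * widen, w_m)
  }
  drop <- jet$core_speed * abs(grid$f) / grid$g *
    jet$cross_width * 1000 * sqrt(2 * pi)
  eta <- drop * (stats::pnorm(s_m / w_m) - 1)
  if (jet$offshore_slope > 0) {
    # smooth one-sided ramp (softplus, 15 km rounding) so the outer-band
    # drift switches on seaward of the axis without a kink
    wr <- 15000
    eta <- eta + jet$offshore_slope * wr * log1p(exp(pmin(s_m / wr, 40)))
  }
  eta
}

# great-circle distance (m) from every grid node to a point
gc_dist_grid <- function(grid, p) {
  pts <- cbind(rep(grid$lon, length(grid$lat)),
               rep(grid$lat, each = length(grid$lon)))
  matrix(gc_distance(pts, p), nrow = length(grid$lon))
}

# eddy_metric() evaluated at every grid node, matrices lon x lat
eddy_metric_grid <- function(scen, grid, t) {
  em <- eddy_metric(scen, rep(grid$lon, length(grid$lat)),
                    rep(grid$lat, each = length(grid$lon)), t)
  list(d_eff_m = matrix(em$d_eff_m, nrow = length(grid$lon)),
       theta = matrix(em$theta, nrow = length(grid$lon)),
       ctr = em$ctr)
}

#' Surface geostrophic velocity from SSH
#'
#' `u = -(g/f) dEta/dy`, `v = (g/f) dEta/dx` by centred differences
#' (one-sided at the domain edges), with the metric terms evaluated at the
#' local latitude. On an f-plane with f < 0 a depression rotates clockwise
#' (a Southern-Hemisphere cyclone).
#'
#' @param eta SSH matrix (lon x lat), metres.
#' @param grid A [grid_spec()]; `grid$f` must be non-zero.
#' @return List with `u`, `v` matrices (m/s).
#' @export
geostrophic_velocity <- function(eta, grid) {
  if (grid$f == 0) stop("f = 0: geostrophic balance undefined")
  nx <- length(grid$lon); ny <- length(grid$lat)
  stopifnot(nrow(eta) == nx, ncol(eta) == ny)
  dx <- outer(rep(1, nx), m_per_deg_lon(grid$lat)) * grid$d_deg
  dy <- EARTH_RADIUS_M * pi / 180 * grid$d_deg
  detadx <- central_diff(eta, 1) / dx
  detady <- central_diff(eta, 2) / dy
  list(u = -(grid$g / grid$f) * detady,
       v = (grid$g / grid$f) * detadx)
}

# centred difference along margin 1 (rows) or 2 (cols); one-sided at edges;
# returns d(eta) per grid step
central_diff <- function(m, margin) {
  if (margin == 2) return(t(central_diff(t(m), 1)))
  n <- nrow(m)
  out <- m
  out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  out[1, ] <- m[2, ] - m[1, ]
  out[n, ] <- m[n, ] - m[n - 1, ]
  out
}

#' Extend a surface velocity field down the water column
#'
#' Surface-intensified exponential decay: `(u, v)(z) = (u_s, v_s) exp(-z/H)`
#' with e-folding depth `H = vert_scale`.
#'
#' @param u_s,v_s Surface velocity matrices (lon x lat), m/s.
#' @param depth Vector of depth levels, m, positive down.
#' @param vert_scale e-folding depth, m (> 0).
#' @return List with `u`, `v` arrays of dims lon x lat x depth.
#' @export
extend_velocity_vertical <- function(u_s, v_s, depth, vert_scale) {
  if (vert_scale <= 0) stop("vert_scale must be positive")
  fac <- exp(-depth / vert_scale)
  u <- outer(u_s, fac)
  v <- outer(v_s, fac)
  list(u = u, v = v)
}

#' Eddy vertical velocity field
#'
#' Sign convention (used consistently throughout the package): depth is
#' positive down and **w > 0 moves particles downward** (downwelling);
#' upwelling is w < 0. The field is
#' `w(r, theta, z) = (-w_up core(r/L) + w0 edge(r/L) m(theta)) p(z)` where
#' `core` peaks at the centre (upwelling), `edge` peaks near `r = L` and
#' vanishes by `r > 2L`, and the azimuthal modulation `m` concentrates the
#' edge downwelling on the trailing edge while the eddy translates
#' (`m = (1 + cos(theta - theta_prop - pi))/2`) and is symmetric
#' (`m = 1/2`) while it is stationary. `p(z)` is finite at the surface
#' (convergence zones displace surface particles), saturates by ~20 m and
#' fades below 250 m. The annulus position and width are set by
#' `w_edge_peak` / `w_edge_width`.
#'
#' @param scen An [eddy_scenario()].
#' @param grid A [grid_spec()].
#' @param t Day.
#' @return Array (lon x lat x depth) of w in m/s, positive down.
#' @export
vertical_velocity <- function(scen, grid, t) {
  sch <- eddy_schedule(scen, t)
  L_m <- sch$L_km * 1000
  em <- eddy_metric_grid(scen, grid, t)
  x <- em$d_eff_m / L_m
  core <- exp(-(x / 0.5)^2 / 2)
  edge <- exp(-((x - scen$w_edge_peak) / scen$w_edge_width)^2 / 2)
  if (sch$c_ms > 0) {
    theta_prop <- (90 - scen$heading) * pi / 180
    m <- (1 + cos(em$theta - theta_prop - pi)) / 2
  } else {
    m <- 0.5
  }
  w_surf <- (-scen$w_up * core + scen$w0 * edge * m) / 86400  # m/day -> m/s
  p <- w_depth_profile(grid$depth)
  outer(w_surf, p)
}

# dimensionless vertical shape of w: finite at the surface (convergence
# zones displace surface particles downward), saturating by 20 m and
# fading below 250 m to 0 by 600 m
w_depth_profile <- function(z) {
  p <- pmin((z + 6) / 26, 1)
  deep <- z > 250
  p[deep] <- pmax(0, 1 - (z[deep] - 250) / 350)
  p
}

#' Stratified temperature field with eddy isotherm doming
#'
#' The far-field profile runs from 22.9 deg C Tropical Water at the surface
#' (mixed layer to 25 m) down to the 12.9 deg C South Atlantic Central
#' Water asymptote through a Gaussian-shaped thermocline. Inside the eddy,
#' isotherms dome upward: the profile is sampled at an effective depth
#' `z + dome_coef * A(t) * exp(-r^2/(2 L^2))`, so cooler water sits
#' shallower in the core in proportion to the SSH depression.
#'
#' @param grid A [grid_spec()].
#' @param scen An [eddy_scenario()] or `NULL` for the far-field profile
#'   everywhere.
#' @param t Day.
#' @return Array (lon x lat x depth) of temperature, deg C.
#' @export
temperature_field <- function(grid, scen, t) {
  nz <- length(grid$depth)
  if (is.null(scen)) {
    dome <- matrix(0, length(grid$lon), length(grid$lat))
  } else {
    sch <- eddy_schedule(scen, t)
    em <- eddy_metric_grid(scen, grid, t)
    dome <- scen$dome_coef * sch$A_m *
      exp(-em$d_eff_m^2 / (2 * (sch$L_km * 1000)^2))
  }
  out <- array(NA_real_, c(dim(dome), nz))
  for (k in seq_len(nz)) {
    out[, , k] <- temp_profile(grid$depth[k] + dome)
  }
  out
}

#' Far-field temperature profile
#'
#' @param z Depth(s) in metres, positive down.
#' @return Temperature in deg C: 22.9 at the surface, 12.9 asymptote.
#' @export
temp_profile <- function(z, t_surf = 22.9, t_deep = 12.9,
                         mixed_layer = 25, thermocline = 120) {
  zz <- pmax(0, z - mixed_layer)
  t_deep + (t_surf - t_deep) * exp(-(zz / thermocline)^2)
}
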