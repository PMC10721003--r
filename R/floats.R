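#' Larval release schedule
#'
#' Surface release from a cluster of three sites centred on the Campos
#' Basin source spot (41.255 W, 23.316 S), the reported planulation event:
#' 3000 larvae per day for 16 days (48,000 in total). The cluster spreads
#' the sites +/- 0.02 degrees in longitude (sub-grid scale).
#'
#' @param center Cluster centre (lon, lat).
#' @param per_day Larvae released per day (must divide equally across the
#'   sites).
#' @param n_days Number of release days.
#' @param release_depth Release depth, m (>= 0; surface release).
#' @param site_offset_deg Longitude offset of the two flanking sites.
#' @return Object of class `release_schedule`.
#' @export
release_schedule <- function(center = c(-41.255, -23.316),
                             per_day = 3000, n_days = 16,
                             release_depth = 0, site_offset_deg = 0.02) {
  center <- unname(center)
  sites <- rbind(center + c(-site_offset_deg, 0),
                 center,
                 center + c(site_offset_deg, 0))
  dimnames(sites) <- NULL
  if (per_day %% nrow(sites) != 0) {
    stop("per_day must be divisible by the number of sites")
  }
  stopifnot(release_depth >= 0, n_days >= 1)
  structure(list(sites = sites, center = center, per_day = as.integer(per_day),
                 n_days = as.integer(n_days), release_depth = release_depth),
            class = "release_schedule")
}

#' Mixing specification
#'
#' Constant-diffusivity random walks (unbiased without a gradient
#' correction precisely because the diffusivities are constant): a
#' vertical walk with reflective surface and bottom boundaries, and an
#' optional horizontal walk standing in for the stirring by unresolved
#' (sub)mesoscale motions that a smooth kinematic flow field lacks.
#'
#' @param K Vertical diffusivity, m^2/s.
#' @param K_h Horizontal diffusivity, m^2/s (0 disables the horizontal
#'   walk; tens of m^2/s is typical for an eddy-resolving grid of this
#'   resolution).
#' @param dt Integration time step, s; must divide 86400.
#' @return Object of class `mixing_spec`.
#' @export
mixing_spec <- function(K = 1e-5, K_h = 0, dt = 1800) {
  stopifnot(K >= 0, K_h >= 0, dt > 0)
  if (86400 %% dt != 0) stop("dt must divide 86400 s")
  structure(list(K = K, K_h = K_h, dt = dt), class = "mixing_spec")
}

#' New particles for one release day
#'
#' @param sched A [release_schedule()].
#' @param t Release day (1-based). Days beyond `n_days` release nothing.
#' @param scale Fraction of `per_day` actually released (scaled-down runs);
#'   the scaled count is rounded to a multiple of the site count.
#' @return Data frame with `lon`, `lat`, `z` for the new particles (zero
#'   rows after the event ends).
#' @export
release <- function(sched, t, scale = 1) {
  n_sites <- nrow(sched$sites)
  n <- if (t >= 1 && t <= sched$n_days) {
    n_sites * round(sched$per_day * scale / n_sites)
  } else 0L
  if (n == 0) {
    return(data.frame(lon = numeric(0), lat = numeric(0), z = numeric(0)))
  }
  idx <- rep(seq_len(n_sites), each = n / n_sites)
  data.frame(lon = sched$sites[idx, 1], lat = sched$sites[idx, 2],
             z = rep(sched$release_depth, n))
}

#' One RK4 horizontal advection step
#'
#' Classical 4-stage Runge-Kutta on the interpolated horizontal velocity,
#' with degrees/metres conversion at each particle's local latitude. Depth
#' is held fixed during the horizontal step (operator splitting with
#' [vertical_step()]). A particle whose trajectory (any stage or the final
#' position) leaves the lateral hull is flagged `exited` and keeps its
#' pre-step position.
#'
#' @param state An [ocean_state()].
#' @param lon,lat,z Particle coordinates.
#' @param tau Time in days at the start of the step.
#' @param dt Step length, s.
#' @return List with `lon`, `lat` (updated) and logical `exited`.
#' @export
rk4_step <- function(state, lon, lat, z, tau, dt) {
  g <- state$grid
  dt_days <- dt / 86400
  in_hull <- function(lo, la) {
    lo >= g$lon[1] & lo <= g$lon[length(g$lon)] &
      la >= g$lat[1] & la <= g$lat[length(g$lat)]
  }
  deg_rate <- function(lo, la, tt) {
    uv <- interp_fields(state, c("u", "v"), lo, la, z, tt)
    list(dlon = uv$u / m_per_deg_lon(la), dlat = uv$v / m_per_deg_lat(la))
  }
  bad <- !in_hull(lon, lat)
  k1 <- deg_rate(lon, lat, tau)
  l2 <- lon + k1$dlon * dt / 2; a2 <- lat + k1$dlat * dt / 2
  bad <- bad | !in_hull(l2, a2)
  l2c <- ifelse(bad, lon, l2); a2c <- ifelse(bad, lat, a2)
  k2 <- deg_rate(l2c, a2c, tau + dt_days / 2)
  l3 <- lon + k2$dlon * dt / 2; a3 <- lat + k2$dlat * dt / 2
  bad <- bad | !in_hull(l3, a3)
  l3c <- ifelse(bad, lon, l3); a3c <- ifelse(bad, lat, a3)
  k3 <- deg_rate(l3c, a3c, tau + dt_days / 2)
  l4 <- lon + k3$dlon * dt; a4 <- lat + k3$dlat * dt
  bad <- bad | !in_hull(l4, a4)
  l4c <- ifelse(bad, lon, l4); a4c <- ifelse(bad, lat, a4)
  k4 <- deg_rate(l4c, a4c, tau + dt_days)
  new_lon <- lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  new_lat <- lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  bad <- bad | !in_hull(new_lon, new_lat)
  list(lon = ifelse(bad, lon, new_lon),
       lat = ifelse(bad, lat, new_lat),
       exited = bad)
}

#' One vertical advection + random-walk step
#'
#' `z' = z + w dt + N(0,1) sqrt(2 K dt)`, then reflection at the surface
#' (z = 0) and at the local bottom, so `z'` stays in `[0, h]`. `w` is
#' positive down.
#'
#' @param z Depths, m (positive down).
#' @param w Vertical velocity at the particles, m/s, positive down.
#' @param mix A [mixing_spec()].
#' @param bottom Local bottom depth(s), m.
#' @param noise Standard-normal draws (one per particle); supplied by the
#'   caller so the simulation owns the RNG stream.
#' @return Updated depths.
#' @export
vertical_step <- function(z, w, mix, bottom, noise = rep(0, length(z))) {
  zn <- z + w * mix$dt + noise * sqrt(2 * mix$K * mix$dt)
  # fold back into [0, bottom]; a couple of passes suffice for any
  # realistic step size
  for (pass in 1:4) {
    zn <- abs(zn)
    over <- zn > bottom
    if (!any(over)) break
    zn[over] <- 2 * bottom[over] - zn[over]
  }
  pmin(pmax(zn, 0), bottom)
}

#' Run the Lagrangian dispersal simulation
#'
#' Releases larvae on the schedule, advances them with RK4 horizontal
#' advection plus vertical advection/random walk at `dt` resolution, and
#' archives daily positions. Deterministic given the seed. Exited larvae
#' are frozen at their last in-domain position (used by all later distance
#' statistics) and excluded from further integration.
#'
#' @param state An [ocean_state()] covering the run window.
#' @param sched A [release_schedule()].
#' @param mix A [mixing_spec()].
#' @param seed RNG seed (integer).
#' @param t_days Number of simulated days (default: the field record
#'   length).
#' @param scale Release scale factor (fraction of `per_day`).
#' @param verbose Print per-day released/active/exited counts.
#' @return Object of class `trajectory_set`: matrices `lon`, `lat`, `z`
#'   (particle x day, NA before release), `release_day`, `status`
#'   (`active`/`exited`), `exit_day` (NA if never exited), plus the run
#'   metadata.
#' @export
run_simulation <- function(state, sched, mix, seed = 1,
                           t_days = length(state$days), scale = 1,
                           verbose = FALSE) {
  if (t_days > max(state$days)) stop("fields do not cover the run window")
  set.seed(as.integer(seed))
  nsub <- 86400 %/% mix$dt
  per_rel <- nrow(release(sched, 1, scale))
  ntot <- per_rel * min(sched$n_days, t_days)
  lon_d <- matrix(NA_real_, ntot, t_days)
  lat_d <- matrix(NA_real_, ntot, t_days)
  z_d <- matrix(NA_real_, ntot, t_days)
  release_day <- integer(0)
  exit_day <- rep(NA_integer_, ntot)
  lon <- lat <- z <- numeric(0)
  active <- logical(0)
  g <- state$grid
  for (day in seq_len(t_days)) {
    newp <- release(sched, day, scale)
    if (nrow(newp)) {
      lon <- c(lon, newp$lon); lat <- c(lat, newp$lat); z <- c(z, newp$z)
      active <- c(active, rep(TRUE, nrow(newp)))
      release_day <- c(release_day, rep(day, nrow(newp)))
    }
    n <- length(lon)
    for (s in seq_len(nsub)) {
      idx <- which(active)
      if (!length(idx)) break
      tau <- (day - 1) + (s - 1) / nsub
      st <- rk4_step(state, lon[idx], lat[idx], z[idx], tau, mix$dt)
      if (mix$K_h > 0) {
        sig <- sqrt(2 * mix$K_h * mix$dt)
        kick_lon <- st$lon + stats::rnorm(length(idx)) * sig /
          m_per_deg_lon(st$lat)
        kick_lat <- st$lat + stats::rnorm(length(idx)) * sig /
          m_per_deg_lat(st$lat)
        in_hull <- kick_lon >= g$lon[1] & kick_lon <= g$lon[length(g$lon)] &
          kick_lat >= g$lat[1] & kick_lat <= g$lat[length(g$lat)]
        keep <- !st$exited & in_hull
        st$lon[keep] <- kick_lon[keep]
        st$lat[keep] <- kick_lat[keep]
        st$exited <- st$exited | !in_hull
      }
      wv <- interp_fields(state, "w", st$lon, st$lat, z[idx], tau)$w
      noise <- stats::rnorm(length(idx))
      bot <- interp_bilinear(state$bathy_h, g$lon, g$lat, st$lon, st$lat)
      bot <- pmax(bot, 1)  # keep a positive reflection depth everywhere
      zn <- vertical_step(z[idx], wv, mix, bot, noise)
      lon[idx] <- st$lon; lat[idx] <- st$lat
      zn[st$exited] <- z[idx][st$exited]
      z[idx] <- zn
      if (any(st$exited)) {
        ex <- idx[st$exited]
        active[ex] <- FALSE
        exit_day[ex] <- day
      }
    }
    rows <- seq_len(n)
    lon_d[rows, day] <- lon; lat_d[rows, day] <- lat; z_d[rows, day] <- z
    if (verbose) {
      message(sprintf("day %2d: released %d, active %d, exited %d",
                      day, n, sum(active), n - sum(active)))
    }
  }
  structure(list(lon = lon_d, lat = lat_d, z = z_d,
                 release_day = release_day,
                 status = ifelse(is.na(exit_day), "active", "exited"),
                 exit_day = exit_day, n = ntot, t_days = t_days,
                 sched = sched, mix = mix, seed = seed, scale = scale),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d larvae over %d days (%d exited), seed %s\n",
              x$n, x$t_days, sum(x$status == "exited"), format(x$seed)))
  invisible(x)
}

#' Tidy per-day trajectory records
#'
#' One row per larva-day from its release day to the end of the run;
#' `status` switches to `exited` from the exit day onward (positions stay
#' frozen at the last in-domain location).
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return Data frame with `id`, `day`, `lon`, `lat`, `z_m`, `age_d`,
#'   `status`.
#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  rows <- which(!is.na(x$lon), arr.ind = TRUE)
  id <- rows[, 1]; day <- rows[, 2]
  ord <- order(id, day)
  id <- id[ord]; day <- day[ord]
  data.frame(id = id, day = day,
             lon = x$lon[cbind(id, day)],
             lat = x$lat[cbind(id, day)],
             z_m = x$z[cbind(id, day)],
             age_d = day - x$release_day[id] + 1,
             status = ifelse(!is.na(x$exit_day[id]) & day >= x$exit_day[id],
                             "exited", "active"))
}

#' Write / read trajectories as tidy CSV
#' @param x A `trajectory_set`.
#' @param path CSV path.
#' @return `path` (write) or the tidy data frame (read), invisibly.
#' @export
write_trajectories <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# larva is in-domain (not yet exited) on a given day
in_domain_on_day <- function(traj, day) {
  !is.na(traj$lon[, day]) &
    (is.na(traj$exit_day) | traj$exit_day > day)
}
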