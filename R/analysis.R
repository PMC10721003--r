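#' Daily capture classification against the tracked eddy contour
#'
#' A larva is "captured" on a day if its recorded position lies inside
#' that day's effective contour (boundary counts as inside). The trapped
#' percentage uses as denominator the larvae released so far and still in
#' the domain. Days without an eddy observation are reported as gaps (NA).
#'
#' @param traj A `trajectory_set`.
#' @param track An `eddy_track` whose observation days align with the
#'   trajectory calendar.
#' @return List with `inside` (larva x day logical matrix, NA where the
#'   larva does not exist or no contour exists), `days_inside` (per-larva
#'   totals), `trapped_pct` and `outside_pct` (per-day, NA on gap days),
#'   `n_in_domain` (per-day denominators).
#' @export
capture_series <- function(traj, track) {
  t_days <- traj$t_days
  day_to_obs <- match(seq_len(t_days), track$obs$day)
  inside <- matrix(NA, traj$n, t_days)
  trapped <- rep(NA_real_, t_days)
  denom <- rep(NA_integer_, t_days)
  for (d in seq_len(t_days)) {
    oi <- day_to_obs[d]
    if (is.na(oi)) next
    ring <- close_ring(track$contours[[oi]])
    if (!is_simple_polygon(ring)) stop("non-simple effective contour on day ", d)
    dom <- in_domain_on_day(traj, d)
    denom[d] <- sum(dom)
    if (!sum(dom)) next
    flags <- point_in_polygon(traj$lon[dom, d], traj$lat[dom, d], ring)
    inside[dom, d] <- flags
    trapped[d] <- 100 * sum(flags) / sum(dom)
  }
  list(inside = inside,
       days_inside = rowSums(inside, na.rm = TRUE),
       trapped_pct = trapped, outside_pct = 100 - trapped,
       n_in_domain = denom)
}

#' Great-circle distance from the release origin
#'
#' Distance from the release-cluster centroid to each larva's position at
#' the end of the run; larvae that left the domain keep their last
#' recorded in-domain position.
#'
#' @param traj A `trajectory_set`.
#' @param origin Lon/lat of the release centroid (default: the schedule's
#'   cluster centre).
#' @param day Day at which positions are taken (default: last day).
#' @return Numeric vector of distances in km (NA for larvae not yet
#'   released by `day`).
#' @export
origin_distance <- function(traj, origin = traj$sched$center,
                            day = traj$t_days) {
  lon <- traj$lon[, day]; lat <- traj$lat[, day]
  out <- rep(NA_real_, traj$n)
  ok <- !is.na(lon)
  out[ok] <- gc_distance(cbind(lon[ok], lat[ok]), origin) / 1000
  out
}

#' Residence-distance correlation
#'
#' Pearson product-moment correlation between the number of days each
#' larva spent inside the eddy and its distance from the release origin at
#' the end of the run. A strongly negative value means the eddy held
#' larvae back relative to the jet-advected ones.
#'
#' @param days_inside Per-larva days-inside totals.
#' @param distance_km Per-larva origin distances.
#' @return Pearson r.
#' @export
residence_distance_correlation <- function(days_inside, distance_km) {
  ok <- !is.na(days_inside) & !is.na(distance_km)
  x <- days_inside[ok]; y <- distance_km[ok]
  if (length(x) < 3) stop("correlation needs at least 3 larvae")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input")
  }
  stats::cor(x, y)
}

#' Depth distribution of larva-day records
#'
#' Pools every in-domain larva-day depth record of the run; the deep
#' fraction is the percentage of records deeper than the threshold.
#'
#' @param traj A `trajectory_set`.
#' @param threshold_m Deep threshold, m (default 60).
#' @param breaks Histogram breaks, m.
#' @return List with `histogram` (counts per bin), `breaks`, `n_records`,
#'   `deep_fraction_pct`.
#' @export
depth_statistics <- function(traj, threshold_m = 60,
                             breaks = seq(0, 600, by = 10)) {
  z <- record_values(traj, traj$z)
  bin <- findInterval(pmin(z, max(breaks) - 1e-9), breaks,
                      rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  list(histogram = counts, breaks = breaks, n_records = length(z),
       deep_fraction_pct = 100 * mean(z > threshold_m))
}

# pool per-day values over in-domain larva-days
record_values <- function(traj, mat) {
  vals <- numeric(0)
  for (d in seq_len(traj$t_days)) {
    dom <- in_domain_on_day(traj, d)
    vals <- c(vals, mat[dom, d])
  }
  vals
}

#' Fraction of deep larvae in the eddy vicinity on one day
#'
#' Among in-domain larvae deeper than the threshold on the given day, the
#' percentage within `factor` effective radii of that day's tracked
#' centroid.
#'
#' @param traj A `trajectory_set`.
#' @param track An `eddy_track`.
#' @param day Analysis day.
#' @param threshold_m Deep threshold, m.
#' @param factor Vicinity radius in units of the effective radius.
#' @return List with `pct` (NA with `n_deep = 0` flag when no larva is
#'   deep that day), `n_deep`, `n_in_vicinity`.
#' @export
vicinity_fraction <- function(traj, track, day, threshold_m = 60,
                              factor = 1.5) {
  oi <- match(day, track$obs$day)
  if (is.na(oi)) stop("no eddy observation on day ", day)
  dom <- in_domain_on_day(traj, day)
  deep <- dom & !is.na(traj$z[, day]) & traj$z[, day] > threshold_m
  n_deep <- sum(deep)
  if (!n_deep) {
    return(list(pct = NA_real_, n_deep = 0L, n_in_vicinity = 0L))
  }
  ctr <- c(track$obs$lon[oi], track$obs$lat[oi])
  d_km <- gc_distance(cbind(traj$lon[deep, day], traj$lat[deep, day]),
                      ctr) / 1000
  n_in <- sum(d_km <= factor * track$obs$radius_km[oi])
  list(pct = 100 * n_in / n_deep, n_deep = n_deep, n_in_vicinity = n_in)
}

#' Cold-water exposure on one day
#'
#' Interpolates the temperature field to every in-domain larva's position
#' and depth and reports the percentage below the threshold.
#'
#' @param traj A `trajectory_set`.
#' @param state The [ocean_state()] the larvae were run in.
#' @param day Analysis day.
#' @param threshold_c Temperature threshold, deg C.
#' @return List with `pct`, `n`, `temps`.
#' @export
cold_exposure <- function(traj, state, day, threshold_c = 20) {
  if (is.null(state$temp)) stop("temperature field missing")
  dom <- in_domain_on_day(traj, day)
  if (!sum(dom)) return(list(pct = NA_real_, n = 0L, temps = numeric(0)))
  tt <- interp_fields(state, "temp", traj$lon[dom, day], traj$lat[dom, day],
                      traj$z[dom, day], day)$temp
  list(pct = 100 * mean(tt < threshold_c), n = sum(dom), temps = tt)
}

#' Coastal arrivals across an isobath
#'
#' A larva counts once if any of its recorded in-domain positions lies
#' where the bathymetry is shallower than the isobath (the coastal-barrier
#' criterion).
#'
#' @param traj A `trajectory_set`.
#' @param state The [ocean_state()] (for bathymetry and grid).
#' @param isobath_m Barrier isobath, m (default 200).
#' @return List with `count` and `ids`.
#' @export
coastal_arrivals <- function(traj, state, isobath_m = 200) {
  g <- state$grid
  hit <- rep(FALSE, traj$n)
  for (d in seq_len(traj$t_days)) {
    dom <- in_domain_on_day(traj, d)
    if (!sum(dom)) next
    h <- interp_bilinear(state$bathy_h, g$lon, g$lat,
                         traj$lon[dom, d], traj$lat[dom, d])
    hit[which(dom)[h < isobath_m]] <- TRUE
  }
  list(count = sum(hit), ids = which(hit))
}

#' Larva-day density map
#'
#' Counts in-domain larva-day records per grid cell (cells centred on the
#' grid nodes); the total equals the number of records.
#'
#' @param traj A `trajectory_set`.
#' @param grid A [grid_spec()].
#' @return Matrix of counts, dims lon x lat.
#' @export
density_map <- function(traj, grid) {
  counts <- matrix(0L, length(grid$lon), length(grid$lat))
  for (d in seq_len(traj$t_days)) {
    dom <- in_domain_on_day(traj, d)
    if (!sum(dom)) next
    i <- round((traj$lon[dom, d] - grid$lon[1]) / grid$d_deg) + 1
    j <- round((traj$lat[dom, d] - grid$lat[1]) / grid$d_deg) + 1
    ok <- i >= 1 & i <= length(grid$lon) & j >= 1 & j <= length(grid$lat)
    tab <- table(factor(i[ok] + (j[ok] - 1) * length(grid$lon),
                        levels = seq_along(counts)))
    counts <- counts + matrix(as.integer(tab), nrow = length(grid$lon))
  }
  counts
}
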