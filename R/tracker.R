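#' Detection parameters for the closed-contour eddy identification
#'
#' The identification criteria follow common practice for SSH-based eddy
#' detection at this grid scale: a contour-level step, a minimum amplitude,
#' pixel-count bounds and a maximum shape error, with the requirement of
#' exactly one SSH extremum inside a qualifying contour.
#'
#' @param contour_interval Level step, m.
#' @param min_amplitude Minimum |extremum - contour level|, m.
#' @param pixel_min,pixel_max Grid-node count bounds inside a contour.
#' @param shape_error_max Maximum shape error, percent.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(contour_interval = 0.002, min_amplitude = 0.01,
                             pixel_min = 8, pixel_max = 1000,
                             shape_error_max = 55) {
  stopifnot(contour_interval > 0, pixel_min < pixel_max, min_amplitude >= 0)
  structure(list(contour_interval = contour_interval,
                 min_amplitude = min_amplitude,
                 pixel_min = pixel_min, pixel_max = pixel_max,
                 shape_error_max = shape_error_max),
            class = "detection_params")
}

#' Local SSH extrema by 8-neighbourhood comparison
#'
#' @param eta SSH matrix (lon x lat).
#' @param grid A [grid_spec()].
#' @param kind `"min"` (cyclonic candidates, the default) or `"max"`.
#' @return Data frame with `i`, `j`, `lon`, `lat`, `value` (possibly zero
#'   rows).
#' @export
find_extrema <- function(eta, grid, kind = c("min", "max")) {
  kind <- match.arg(kind)
  z <- if (kind == "min") eta else -eta
  nx <- nrow(z); ny <- ncol(z)
  pad <- matrix(Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- z
  is_min <- matrix(TRUE, nx, ny)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pad[(2:(nx + 1)) + di, (2:(ny + 1)) + dj]
      is_min <- is_min & (z < nb)
    }
  }
  idx <- which(is_min, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             lon = grid$lon[idx[, 1]], lat = grid$lat[idx[, 2]],
             value = eta[idx])
}

#' Closed SSH contours at given levels
#'
#' Extracts all contours and keeps the ones that close inside the domain
#' (first and last vertex coincide); boundary-truncated contours are
#' discarded.
#'
#' @param eta SSH matrix (lon x lat).
#' @param grid A [grid_spec()].
#' @param levels Contour levels, m.
#' @return List of lists with `level` and `ring` (lon/lat matrix).
#' @export
extract_closed_contours <- function(eta, grid, levels) {
  cl <- grDevices::contourLines(grid$lon, grid$lat, eta, levels = levels)
  out <- list()
  for (ci in cl) {
    n <- length(ci$x)
    if (n < 4) next
    closed <- abs(ci$x[1] - ci$x[n]) < 1e-9 && abs(ci$y[1] - ci$y[n]) < 1e-9
    if (!closed) next
    out[[length(out) + 1]] <- list(level = ci$level,
                                   ring = cbind(lon = ci$x, lat = ci$y))
  }
  out
}

#' Qualify a candidate contour
#'
#' A contour qualifies if the grid-node count inside is within the pixel
#' bounds, the amplitude |extremum - level| meets the minimum, exactly one
#' extremum lies inside, and the shape error against the best-fit circle
#' does not exceed the maximum.
#'
#' @param ring Lon/lat matrix of the closed contour.
#' @param level Contour level, m.
#' @param eta SSH matrix.
#' @param grid A [grid_spec()].
#' @param extrema Data frame from [find_extrema()].
#' @param params A [detection_params()].
#' @return List with `ok` (logical), `reasons` (character), and the
#'   computed `n_pixels`, `amplitude`, `shape_err`, `extrema_inside`
#'   (row indices of `extrema`).
#' @export
qualify <- function(ring, level, eta, grid, extrema, params) {
  reasons <- character(0)
  if (nrow(ring) < 4) {
    return(list(ok = FALSE, reasons = "degenerate polygon (<4 vertices)",
                n_pixels = NA, amplitude = NA, shape_err = NA,
                extrema_inside = integer(0)))
  }
  ex_in <- unname(which(point_in_polygon(extrema$lon, extrema$lat, ring)))
  if (length(ex_in) != 1) {
    reasons <- c(reasons, if (length(ex_in) == 0) "no extremum inside"
                 else "multiple extrema")
  }
  # pixel count restricted to the contour bounding box
  ii <- which(grid$lon >= min(ring[, 1]) & grid$lon <= max(ring[, 1]))
  jj <- which(grid$lat >= min(ring[, 2]) & grid$lat <= max(ring[, 2]))
  n_pix <- if (length(ii) && length(jj)) {
    pts <- expand.grid(lon = grid$lon[ii], lat = grid$lat[jj])
    sum(point_in_polygon(pts$lon, pts$lat, ring))
  } else 0L
  if (n_pix < params$pixel_min) reasons <- c(reasons, "too few pixels")
  if (n_pix > params$pixel_max) reasons <- c(reasons, "too many pixels")
  amp <- if (length(ex_in) >= 1) {
    max(abs(extrema$value[ex_in] - level))
  } else NA_real_
  if (!is.na(amp) && amp < params$min_amplitude) {
    reasons <- c(reasons, "amplitude below threshold")
  }
  se <- shape_error(ring)
  if (se > params$shape_error_max) reasons <- c(reasons, "shape error")
  list(ok = length(reasons) == 0, reasons = reasons, n_pixels = n_pix,
       amplitude = amp, shape_err = se, extrema_inside = ex_in)
}

#' Identify eddies in one SSH snapshot
#'
#' For each SSH minimum, contour levels step upward from the minimum by
#' `contour_interval`; the effective contour is the outermost (largest
#' area) qualifying contour around that single extremum, the effective
#' radius is the equal-area circle radius, the amplitude is
#' |extremum - effective level|, and the swirl speed U is the maximum over
#' qualifying contours of the length-weighted mean geostrophic speed along
#' the contour (the maximum circum-averaged speed within the eddy).
#'
#' @param eta SSH matrix (lon x lat).
#' @param grid A [grid_spec()].
#' @param params A [detection_params()].
#' @param t Day stamp attached to the observations.
#' @return List of eddy observations (class `eddy_observation`): `t`,
#'   `centroid`, `amplitude`, `radius_km`, `contour`, `U`, `shape_err`,
#'   `n_pixels`, `level`.
#' @export
assemble_eddy <- function(eta, grid, params, t = NA_real_) {
  extrema <- find_extrema(eta, grid, "min")
  if (!nrow(extrema)) return(list())
  uv <- geostrophic_velocity(eta, grid)
  lev_lo <- floor(min(extrema$value) / params$contour_interval) *
    params$contour_interval + params$contour_interval
  levels <- seq(lev_lo, max(eta), by = params$contour_interval)
  contours <- extract_closed_contours(eta, grid, levels)
  obs <- list()
  for (e in seq_len(nrow(extrema))) {
    best <- NULL; best_area <- -Inf; u_max <- 0
    for (ct in contours) {
      if (ct$level <= extrema$value[e]) next
      q <- qualify(ct$ring, ct$level, eta, grid, extrema, params)
      if (!q$ok || length(q$extrema_inside) != 1 ||
          q$extrema_inside[1] != e) next
      u_c <- contour_mean_speed(ct$ring, uv, grid)
      u_max <- max(u_max, u_c)
      geo <- polygon_geometry(ct$ring)
      if (geo$area_km2 > best_area) {
        best_area <- geo$area_km2
        best <- list(ct = ct, q = q, geo = geo)
      }
    }
    if (is.null(best)) next
    obs[[length(obs) + 1]] <- structure(
      list(t = t, centroid = best$geo$centroid,
           amplitude = abs(extrema$value[e] - best$ct$level),
           radius_km = sqrt(best$geo$area_km2 / pi),
           contour = best$ct$ring, U = u_max,
           shape_err = best$q$shape_err, n_pixels = best$q$n_pixels,
           level = best$ct$level),
      class = "eddy_observation")
  }
  obs
}

# length-weighted mean of the bilinear geostrophic speed along a ring
contour_mean_speed <- function(ring, uv, grid) {
  ring <- close_ring(ring)
  u <- interp_bilinear(uv$u, grid$lon, grid$lat, ring[, 1], ring[, 2])
  v <- interp_bilinear(uv$v, grid$lon, grid$lat, ring[, 1], ring[, 2])
  sp <- sqrt(u^2 + v^2)
  xy <- local_xy_km(ring[, 1], ring[, 2], mean(ring[, 1]), mean(ring[, 2]))
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  mid <- (sp[-1] + sp[-length(sp)]) / 2
  if (sum(seg) == 0) return(mean(sp))
  sum(mid * seg) / sum(seg)
}

#' Detect eddies in every daily SSH snapshot
#'
#' @param state An [ocean_state()] (or any object with `ssh`, `grid`,
#'   `days`).
#' @param params A [detection_params()].
#' @param verbose Log the per-day detections.
#' @return List (one element per day) of observation lists.
#' @export
detect_eddies <- function(state, params = detection_params(),
                          verbose = FALSE) {
  out <- vector("list", length(state$days))
  for (i in seq_along(state$days)) {
    out[[i]] <- assemble_eddy(state$ssh[, , i], state$grid, params,
                              t = state$days[i])
    if (verbose) {
      message(sprintf("day %2d: %d eddy observation(s)", state$days[i],
                      length(out[[i]])))
    }
  }
  out
}

#' Associate daily observations into tracks
#'
#' Day-to-day association minimises a similarity cost: the mean of the
#' gate-normalised centroid distance, the area-ratio deviation and the
#' amplitude-ratio deviation. Associations beyond the distance gate are
#' rejected; a track with no match terminates (no gap bridging). For small
#' candidate sets the assignment is exhaustive over permutations, making
#' the result independent of candidate order; ties break on smallest cost
#' then smallest centroid distance.
#'
#' @param obs_by_day List of per-day observation lists from
#'   [detect_eddies()].
#' @param gate_km Maximum day-to-day centroid displacement, km.
#' @return List of tracks (class `eddy_track`), longest first. Each track
#'   has a data frame `obs` (day, lon, lat, amplitude, radius_km, U,
#'   shape_err, n_pixels, c_ms, cumulative_km) and the list of `contours`.
#' @export
track_eddies <- function(obs_by_day, gate_km = 150) {
  tracks <- list()   # each: list(obs_idx = list of (day, obs)), open flag
  open_heads <- list()
  for (d in seq_along(obs_by_day)) {
    todays <- obs_by_day[[d]]
    n_new <- length(todays)
    n_open <- length(open_heads)
    assign_new <- rep(NA_integer_, n_new)
    if (n_open > 0 && n_new > 0) {
      cost <- matrix(Inf, n_open, n_new)
      dist <- matrix(Inf, n_open, n_new)
      for (a in seq_len(n_open)) {
        prev <- open_heads[[a]]$last
        for (b in seq_len(n_new)) {
          oo <- todays[[b]]
          dk <- gc_distance(prev$centroid, oo$centroid) / 1000
          dist[a, b] <- dk
          if (dk > gate_km) next
          r_area <- (oo$radius_km / prev$radius_km)^2
          r_amp <- oo$amplitude / prev$amplitude
          cost[a, b] <- (dk / gate_km + abs(r_area - 1) + abs(r_amp - 1)) / 3
        }
      }
      sol <- best_assignment(cost, dist)
      for (a in seq_len(n_open)) {
        if (!is.na(sol[a])) assign_new[sol[a]] <- a
      }
    }
    new_heads <- list()
    for (b in seq_len(n_new)) {
      if (!is.na(assign_new[b])) {
        h <- open_heads[[assign_new[b]]]
        h$obs[[length(h$obs) + 1]] <- todays[[b]]
        h$last <- todays[[b]]
        new_heads[[length(new_heads) + 1]] <- h
      } else {
        new_heads[[length(new_heads) + 1]] <-
          list(obs = list(todays[[b]]), last = todays[[b]])
      }
    }
    # heads not matched today terminate
    if (n_open > 0) {
      for (a in seq_len(n_open)) {
        if (!(a %in% assign_new[!is.na(assign_new)])) {
          tracks[[length(tracks) + 1]] <- open_heads[[a]]
        }
      }
    }
    open_heads <- new_heads
  }
  tracks <- c(tracks, open_heads)
  tracks <- lapply(tracks, finalise_track)
  tracks[order(-vapply(tracks, function(t) nrow(t$obs), numeric(1)))]
}

# exhaustive minimal-cost assignment of rows (open heads) to columns (new
# observations); returns, per row, the assigned column or NA. Falls back
# to greedy nearest-cost for large sets.
best_assignment <- function(cost, dist) {
  n_a <- nrow(cost); n_b <- ncol(cost)
  if (n_a <= 6 && n_b <= 6) {
    cols <- c(seq_len(n_b), rep(NA_integer_, n_a))  # NA = unmatched
    combos <- all_injections(n_a, n_b)
    best <- NULL; best_cost <- Inf; best_dist <- Inf
    for (k in seq_len(nrow(combos))) {
      sel <- combos[k, ]
      cc <- 0; dd <- 0; feasible <- TRUE
      for (a in seq_len(n_a)) {
        if (is.na(sel[a])) next
        if (!is.finite(cost[a, sel[a]])) { feasible <- FALSE; break }
        cc <- cc + cost[a, sel[a]]
        dd <- dd + dist[a, sel[a]]
      }
      if (!feasible) next
      # prefer more matches, then lower cost, then lower distance
      nm <- sum(!is.na(sel))
      key <- c(-nm, cc, dd)
      if (is.null(best) || lex_less(key, best)) {
        best <- key; best_cost <- cc; best_dist <- dd
        best_sel <- sel
      }
    }
    if (is.null(best)) rep(NA_integer_, n_a) else best_sel
  } else {
    sel <- rep(NA_integer_, n_a)
    used <- logical(n_b)
    ord <- order(cost)
    for (k in ord) {
      if (!is.finite(cost[k])) break
      a <- (k - 1) %% n_a + 1; b <- (k - 1) %/% n_a + 1
      if (is.na(sel[a]) && !used[b]) { sel[a] <- b; used[b] <- TRUE }
    }
    sel
  }
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

# all partial injective maps rows -> columns (NA allowed), as a matrix
all_injections <- function(n_a, n_b) {
  opts <- c(NA_integer_, seq_len(n_b))
  grids <- do.call(expand.grid, rep(list(opts), n_a))
  keep <- apply(grids, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) == length(unique(r))
  })
  as.matrix(grids[keep, , drop = FALSE])
}

finalise_track <- function(head) {
  obs <- head$obs
  df <- data.frame(
    day = vapply(obs, function(o) o$t, numeric(1)),
    lon = vapply(obs, function(o) o$centroid[1], numeric(1)),
    lat = vapply(obs, function(o) o$centroid[2], numeric(1)),
    amplitude = vapply(obs, function(o) o$amplitude, numeric(1)),
    radius_km = vapply(obs, function(o) o$radius_km, numeric(1)),
    U = vapply(obs, function(o) o$U, numeric(1)),
    shape_err = vapply(obs, function(o) o$shape_err, numeric(1)),
    n_pixels = vapply(obs, function(o) o$n_pixels, numeric(1)))
  step_km <- if (nrow(df) < 2) rep(NA_real_, nrow(df)) else {
    c(NA, gc_distance(cbind(df$lon[-nrow(df)], df$lat[-nrow(df)]),
                      cbind(df$lon[-1], df$lat[-1])) / 1000)
  }
  dt_days <- c(NA, diff(df$day))
  df$c_ms <- step_km * 1000 / (dt_days * 86400)
  df$cumulative_km <- cumsum(ifelse(is.na(step_km), 0, step_km))
  structure(list(obs = df,
                 contours = lapply(obs, function(o) o$contour)),
            class = "eddy_track")
}

#' @export
print.eddy_track <- function(x, ...) {
  cat(sprintf(
    "<eddy_track> %d days, mean radius %.1f km, cumulative %.0f km\n",
    nrow(x$obs), mean(x$obs$radius_km), max(x$obs$cumulative_km)))
  invisible(x)
}

#' Nonlinearity ratio U/c along a track
#'
#' The ratio of swirl speed to translation speed, day by day where the
#' translation is defined and non-zero; U/c > 1 marks an eddy able to trap
#' and transport the fluid (and plankton) in its interior.
#'
#' @param track An `eddy_track`.
#' @return List with `series` (data frame day, U, c_ms, U_over_c),
#'   `summary` (mean, sd, min, max), and `n_zero_c` (days dropped for
#'   zero translation). `series` has zero rows (with `all_zero_c = TRUE`)
#'   if translation never happens.
#' @export
nonlinearity <- function(track) {
  df <- track$obs
  ok <- !is.na(df$c_ms) & df$c_ms > 0
  ser <- data.frame(day = df$day[ok], U = df$U[ok], c_ms = df$c_ms[ok],
                    U_over_c = df$U[ok] / df$c_ms[ok])
  n_zero <- sum(!is.na(df$c_ms) & df$c_ms == 0)
  summ <- if (nrow(ser)) {
    c(mean = mean(ser$U_over_c), sd = stats::sd(ser$U_over_c),
      min = min(ser$U_over_c), max = max(ser$U_over_c))
  } else c(mean = NA, sd = NA, min = NA, max = NA)
  list(series = ser, summary = summ, n_zero_c = n_zero,
       all_zero_c = nrow(ser) == 0)
}

#' Logistic fit to a radius growth series
#'
#' Least-squares fit of `R(t) = R0 Rinf exp(k t) / (Rinf + R0 (exp(k t)-1))`
#' (t measured from the first observation). The plateau day is the first
#' day the fitted curve reaches 95% of its asymptote.
#'
#' @param days Observation days.
#' @param radius_km Radii, km.
#' @return List with `k` (day^-1), `r_squared`, `plateau_day`, `R0`,
#'   `Rinf`.
#' @export
fit_growth <- function(days, radius_km) {
  if (length(days) < 5) stop("growth fit needs at least 5 points")
  t0 <- days - days[1]
  if (stats::sd(radius_km) < 1e-8) {
    return(list(k = 0, r_squared = 1, plateau_day = days[1],
                R0 = radius_km[1], Rinf = radius_km[1]))
  }
  start <- list(R0 = max(radius_km[1], 1e-3),
                Rinf = max(radius_km) * 1.05, k = 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      radius_km ~ R0 * Rinf * exp(k * t0) / (Rinf + R0 * (exp(k * t0) - 1)),
      start = start, data = data.frame(radius_km = radius_km, t0 = t0),
      lower = c(R0 = 1e-3, Rinf = 1e-3, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("growth fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  pred <- stats::predict(fit)
  r2 <- 1 - sum((radius_km - pred)^2) / sum((radius_km - mean(radius_km))^2)
  # first day the fitted curve reaches 95% of the asymptote
  tt <- seq(0, max(t0) + 60, by = 0.25)
  rv <- cf["R0"] * cf["Rinf"] * exp(cf["k"] * tt) /
    (cf["Rinf"] + cf["R0"] * (exp(cf["k"] * tt) - 1))
  hit <- which(rv >= 0.95 * cf["Rinf"])
  plateau <- if (length(hit)) days[1] + tt[hit[1]] else NA_real_
  list(k = unname(cf["k"]), r_squared = r2, plateau_day = plateau,
       R0 = unname(cf["R0"]), Rinf = unname(cf["Rinf"]))
}
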