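#' Boundary-jet specification
#'
#' A surface-intensified southward jet with a Gaussian cross-stream profile,
#' anchored on the 1000 m isobath of the synthetic bathymetry (where the
#' Brazil Current core sits) and decaying with depth on an e-folding scale.
#' The jet is encoded through its sea-surface-height signature so that the
#' derived geostrophic velocities are exactly consistent with SSH.
#'
#' @param core_speed Surface core speed, m/s (> 0.5 m/s at the shelf break).
#' @param cross_width Cross-stream Gaussian scale sigma, km (speed falls to
#'   exp(-1/2) of the core one sigma away).
#' @param vert_scale e-folding depth of the velocity, m.
#' @param axis_isobath_m Isobath (m) on which the jet core is centred.
#' @param taper_lon,widen_factor Downstream broadening of the jet: west of
#'   `taper_lon` the cross-stream width grows smoothly toward
#'   `widen_factor` times its value at constant transport, so the current
#'   slows and fans seaward as it leaves the study region.
#'   `widen_factor = 1` disables it.
#' @param offshore_slope Weak linear SSH rise offshore of the jet axis
#'   (m per m), representing the broad outer band of the boundary-current
#'   system: it adds a uniform along-coast geostrophic drift
#'   `(g/|f|) offshore_slope` seaward of the jet. 0 disables it.
#' @return Object of class `jet_spec`.
#' @export
jet_spec <- function(core_speed = 0.6, cross_width = 30, vert_scale = 500,
                     axis_isobath_m = 1000, offshore_slope = 0,
                     taper_lon = -43.5, widen_factor = 1) {
  stopifnot(core_speed > 0, cross_width > 0, vert_scale > 0,
            offshore_slope >= 0, widen_factor >= 1)
  structure(list(core_speed = core_speed, cross_width = cross_width,
                 vert_scale = vert_scale, axis_isobath_m = axis_isobath_m,
                 offshore_slope = offshore_slope, taper_lon = taper_lon,
                 widen_factor = widen_factor),
            class = "jet_spec")
}

#' Cyclonic eddy scenario: schedules for the Cape Frio eddy
#'
#' The eddy is a Gaussian SSH depression with a logistic horizontal-scale
#' schedule (quasi-stationary growth saturating mid-run), an amplitude
#' schedule slaved to a target swirl-speed schedule, and a two-phase
#' translation schedule (slow south-westward drift while growing, then a
#' ramping translation as the Brazil Current advects it away).
#'
#' @param center0 Initial centre (lon, lat); default 42 W, 24.2 S.
#' @param L0,Linf,growth_k Logistic schedule of the Gaussian scale L(t) in
#'   km: `L(t) = L0*Linf*exp(k t)/(Linf + L0*(exp(k t)-1))`.
#' @param U0,Uinf Logistic schedule (same rate `growth_k`) of the target
#'   peak swirl speed (m/s) used to derive the amplitude schedule
#'   `A(t) = U(t) L(t) |f| sqrt(e) / g` (the Gaussian-eddy closed form).
#' @param stationary_days Length of the quasi-stationary growth phase.
#' @param c_slow Translation speed during the quasi-stationary phase, m/s.
#' @param c_fast Translation speed reached on the last day, m/s (linear
#'   ramp from `c_slow` after `stationary_days`).
#' @param heading Translation heading, degrees clockwise from north
#'   (225 = south-west).
#' @param k_U Logistic rate of the swirl schedule (defaults to
#'   `growth_k`).
#' @param w0 Edge downwelling amplitude, m/day (positive down).
#' @param w_edge_peak,w_edge_width Radial position and width (in units of
#'   L) of the edge-downwelling annulus.
#' @param w_up Core upwelling amplitude, m/day (applied as negative w).
#' @param dome_coef Isotherm doming, metres of upward isotherm displacement
#'   at the eddy centre per metre of SSH depression.
#' @param shield_amp Relative amplitude of a broad opposing SSH ring
#'   (a "shielded" vortex with near-zero net vorticity): the depression
#'   shape becomes `exp(-x^2/2) - shield_amp exp(-x^2/(2 shield_width^2))`
#'   with `x = d/L`. 0 (the default) is the pure Gaussian monopole.
#' @param shield_width Width of the shield ring in units of L.
#' @param ellipticity Weak ellipticity of the depression (semi-axes
#'   `L (1 +/- ellipticity)`); together with `precess_deg_day` (rotation
#'   rate of the major axis) it makes the edge flow unsteady, giving the
#'   edge exchange a real eddy has. 0 = circular.
#' @param precess_deg_day Precession rate of the major axis, deg/day.
#' @param f,g Coriolis parameter and gravity used to slave A(t) to U(t);
#'   take them from the grid in use.
#' @return Object of class `eddy_scenario` with vectorised schedule
#'   accessors stored as parameters.
#' @export
eddy_scenario <- function(center0 = c(-42.0, -24.2),
                          L0 = 22, Linf = 40, growth_k = 0.052,
                          U0 = 0.40, Uinf = 1.6, k_U = growth_k,
                          stationary_days = 15,
                          c_slow = 0.045, c_fast = 0.17, heading = 225,
                          w0 = 20, w_edge_peak = 1, w_edge_width = 0.35,
                          w_up = 5, dome_coef = 400,
                          shield_amp = 0, shield_width = 2.2,
                          ellipticity = 0, precess_deg_day = 0,
                          f = -2 * 7.2921e-5 * sin(23.5 * pi / 180),
                          g = 9.81) {
  stopifnot(L0 > 0, Linf >= L0, growth_k >= 0, U0 > 0, k_U >= 0,
            stationary_days >= 0, c_slow >= 0, c_fast >= 0,
            w0 >= 0, w_edge_peak > 0, w_edge_width > 0,
            w_up >= 0, dome_coef >= 0,
            shield_amp >= 0, shield_amp < 1, shield_width > 1,
            ellipticity >= 0, ellipticity < 1)
  structure(list(center0 = center0, L0 = L0, Linf = Linf,
                 growth_k = growth_k, U0 = U0, Uinf = Uinf, k_U = k_U,
                 stationary_days = stationary_days,
                 c_slow = c_slow, c_fast = c_fast, heading = heading,
                 w0 = w0, w_edge_peak = w_edge_peak,
                 w_edge_width = w_edge_width,
                 w_up = w_up, dome_coef = dome_coef,
                 shield_amp = shield_amp, shield_width = shield_width,
                 ellipticity = ellipticity,
                 precess_deg_day = precess_deg_day,
                 f = f, g = g),
            class = "eddy_scenario")
}

logistic_curve <- function(t, y0, yinf, k) {
  y0 * yinf * exp(k * t) / (yinf + y0 * (exp(k * t) - 1))
}

#' Eddy schedules at a given day
#'
#' @param scen An [eddy_scenario()].
#' @param t Day (numeric, may be fractional), 0 <= t <= run length.
#' @return List with `L_km` (Gaussian scale), `A_m` (SSH depression
#'   amplitude), `U_target` (peak swirl speed implied by the closed form)
#'   and `c_ms` (translation speed).
#' @export
eddy_schedule <- function(scen, t) {
  L <- logistic_curve(t, scen$L0, scen$Linf, scen$growth_k)
  U <- logistic_curve(t, scen$U0, scen$Uinf, scen$k_U)
  A <- U * (L * 1000) * abs(scen$f) * sqrt(exp(1)) / scen$g
  list(L_km = L, A_m = A, U_target = U, c_ms = eddy_translation_speed(scen, t))
}

#' Elliptical eddy metric distance
#'
#' Effective radial coordinate of points relative to the (possibly
#' elliptical, precessing) depression at day `t`: distances are measured
#' in a local plane about the scheduled centre, scaled by the semi-axes
#' `L (1 + e)` (major, at phase angle `precess_deg_day * t`) and
#' `L (1 - e)` (minor), and re-expressed in metres so that
#' `exp(-d_eff^2 / (2 (L 1000)^2))` is the eddy shape function.
#'
#' @param scen An [eddy_scenario()].
#' @param lon,lat Point coordinates (vectors).
#' @param t Day.
#' @return List with `d_eff_m` (effective distance, m), `theta` (local
#'   plane azimuth, rad) and `ctr` (centre lon/lat).
#' @export
eddy_metric <- function(scen, lon, lat, t) {
  ctr <- eddy_center(scen, t)
  xy <- local_xy_km(lon, lat, ctr[1], ctr[2])
  x <- xy[, 1] * 1000; y <- xy[, 2] * 1000
  e <- scen$ellipticity
  if (e > 0) {
    phi <- scen$precess_deg_day * t * pi / 180
    xr <- x * cos(phi) + y * sin(phi)
    yr <- -x * sin(phi) + y * cos(phi)
    d2 <- (xr / (1 + e))^2 + (yr / (1 - e))^2
  } else {
    d2 <- x^2 + y^2
  }
  list(d_eff_m = sqrt(d2), theta = atan2(y, x), ctr = ctr)
}

# translation speed (m/s) at day t (vectorised)
eddy_translation_speed <- function(scen, t) {
  ramp_len <- 30 - scen$stationary_days
  ifelse(t <= scen$stationary_days | ramp_len <= 0,
         scen$c_slow,
         scen$c_slow + (scen$c_fast - scen$c_slow) *
           pmin(1, (t - scen$stationary_days) / ramp_len))
}

#' Eddy centre position at a given day
#'
#' The centre drifts along the scenario heading by the time-integral of the
#' translation-speed schedule (trapezoidal integration at 0.1-day
#' resolution, so fractional days interpolate smoothly).
#'
#' @param scen An [eddy_scenario()].
#' @param t Day, `0 <= t` (scalar or vector).
#' @param t_max Upper bound for the valid range check (default 60).
#' @return Matrix of lon, lat (one row per `t`).
#' @export
eddy_center <- function(scen, t, t_max = 60) {
  if (any(t < 0 | t > t_max)) stop("day t out of range")
  out <- matrix(NA_real_, length(t), 2, dimnames = list(NULL, c("lon", "lat")))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti == 0) {
      out[i, ] <- scen$center0
      next
    }
    tt <- seq(0, ti, length.out = max(2, ceiling(ti / 0.1) + 1))
    cc <- eddy_translation_speed(scen, tt)
    dist_m <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt)) * 86400
    out[i, ] <- gc_destination(scen$center0, scen$heading, dist_m)
  }
  out
}
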