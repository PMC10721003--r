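# Reference scenario: Brazil-Current jet + Cape Frio cyclonic eddy,
# 16-day planulation event. All parameters of the study conditions live
# here; seed and scale can be overridden at run time.

grid:
  lon_min: -49.0
  lon_max: -37.0
  lat_min: -28.5
  lat_max: -21.1
  d_deg: 0.0833333333333333   # 1/12 degree
  depth_levels: [0, 5, 10, 20, 30, 40, 60, 80, 100, 150, 300, 600]
  t_days: 30
  lat_f: -23.5                # f-plane latitude

bathy:
  shelf_width_km: 72          # coast -> 200 m isobath
  slope_width_km: 138         # 200 m -> abyss
  max_depth_m: 3000

jet:
  core_speed: 0.6             # m/s at the surface core
  cross_width: 30             # km, Gaussian sigma
  vert_scale: 500             # m, e-folding depth
  axis_isobath_m: 1000        # jet core anchored on this isobath
  offshore_slope: 1.0e-7         # SSH rise (m/m) seaward of the axis
  widen_factor: 1.6
  taper_lon: -44.5

eddy:
  center0: [-41.95, -24.35]
  L0: 29.0                    # km, Gaussian scale at day 0
  Linf: 31.5                  # km, logistic asymptote
  growth_k: 0.048             # day^-1
  U0: 0.72                    # m/s, target swirl at day 0
  Uinf: 1.3                   # m/s, swirl logistic asymptote
  stationary_days: 13
  c_slow: 0.052               # m/s, quasi-stationary drift
  c_fast: 0.17                # m/s, reached on day 30
  heading: 225                # degrees true (south-west)
  w0: 6.5                     # m/day edge downwelling
  w_up: 8                     # m/day core upwelling
  dome_coef: 460              # m isotherm doming per m SSH depression
  w_edge_peak: 1.45           # edge-downwelling annulus position, units of L
  w_edge_width: 0.5           # annulus width, units of L
  k_U: 0.052                  # day^-1, swirl logistic rate
  shield_amp: 0.0             # shielded-vortex ring amplitude (off)
  shield_width: 2.2
  ellipticity: 0.08           # weak elliptical distortion of the depression
  precess_deg_day: 40         # deg/day precession of the major axis

release:
  center: [-41.255, -23.316]
  per_day: 3000
  n_days: 16
  release_depth: 0
  site_offset_deg: 0.02

mixing:
  K: 1.0e-5                   # m^2/s vertical diffusivity
  K_h: 55.0                   # m^2/s horizontal (submesoscale) diffusivity
  dt: 1800                    # s

detection:
  contour_interval: 0.002     # m
  min_amplitude: 0.01         # m
  pixel_min: 8
  pixel_max: 1000
  shape_error_max: 55         # percent

analysis:
  depth_threshold_m: 60
  temp_threshold_c: 20
  vicinity_factor: 1.5
  vicinity_day: 15
  cold_day: 26
  capture_day: 10
  outside_day: 16
  isobath_m: 200

run:
  scale: 1.0
  seed: 1
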