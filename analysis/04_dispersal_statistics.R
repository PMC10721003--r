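#!/usr/bin/env Rscript
# Stage 4: combine the larval trajectories with the eddy track to compute
# the dispersal statistics: daily trapped fractions, residence-distance
# correlation, depth and temperature exposure, vicinity analysis, coastal
# arrivals, and the larva-day density map. Also draws the four summary
# figures (capture series, depth histogram, residence vs distance,
# density map).
#
# Outputs: results/dispersal_summary.json, results/daily_fractions.csv,
#          results/density.nc, results/figures/*.png

suppressMessages({
  library(cfeddy)
  library(ggplot2)
})
state <- readRDS("results/fields.rds")
traj <- readRDS("results/trajectories.rds")
cfg <- load_scenario_config()
an <- cfg$analysis

track_obs <- read.csv("results/track.csv")
gj <- jsonlite::read_json("results/contours.geojson")
contours <- lapply(gj$features, function(f) {
  do.call(rbind, lapply(f$geometry$coordinates[[1]],
                        function(p) c(p[[1]], p[[2]])))
})
track <- structure(list(obs = track_obs, contours = contours),
                   class = "eddy_track")

cap <- capture_series(traj, track)
dist_km <- origin_distance(traj)
r <- residence_distance_correlation(cap$days_inside, dist_km)
depth <- depth_statistics(traj, an$depth_threshold_m)
vic <- vicinity_fraction(traj, track, an$vicinity_day,
                         an$depth_threshold_m, an$vicinity_factor)
cold <- cold_exposure(traj, state, an$cold_day, an$temp_threshold_c)
coast <- coastal_arrivals(traj, state, an$isobath_m)
dens <- density_map(traj, state$grid)

daily <- data.frame(day = seq_len(traj$t_days),
                    inside_pct = cap$trapped_pct,
                    outside_pct = cap$outside_pct,
                    n_in_domain = cap$n_in_domain)
write.csv(daily, "results/daily_fractions.csv", row.names = FALSE)

jsonlite::write_json(list(
  trapped_pct_day10 = cap$trapped_pct[an$capture_day],
  outside_pct_day16 = 100 - cap$trapped_pct[an$outside_day],
  trapped_pct_day30 = cap$trapped_pct[traj$t_days],
  pearson_r = r,
  deep_fraction_pct = depth$deep_fraction_pct,
  vicinity_pct_day15 = vic$pct, vicinity_n_deep = vic$n_deep,
  cold_pct_day26 = cold$pct,
  coastal_arrivals = coast$count,
  max_origin_km = max(dist_km, na.rm = TRUE),
  n_larvae = traj$n, n_exited = sum(traj$status == "exited")),
  "results/dispersal_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

# density map as NetCDF
grid <- state$grid
dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
v <- ncdf4::ncvar_def("larva_days", "count", list(dlon, dlat),
                      prec = "integer")
nc <- ncdf4::nc_create("results/density.nc", list(v))
ncdf4::ncvar_put(nc, v, dens)
ncdf4::nc_close(nc)

dir.create("results/figures", showWarnings = FALSE)
theme_set(theme_minimal())

ggsave("results/figures/capture_series.png", width = 7, height = 4, plot =
  ggplot(daily, aes(day)) +
    geom_area(aes(y = inside_pct), fill = "steelblue", alpha = 0.6) +
    geom_line(aes(y = inside_pct), colour = "steelblue4") +
    geom_vline(xintercept = 16, linetype = "dashed") +
    labs(x = "simulation day", y = "% of in-domain larvae inside the eddy",
         title = "Larval capture by the cyclonic eddy",
         subtitle = "dashed line: end of the release window"))

depth_df <- data.frame(mid = head(depth$breaks, -1) + 5,
                       count = depth$histogram)
ggsave("results/figures/depth_histogram.png", width = 6, height = 4, plot =
  ggplot(subset(depth_df, count > 0), aes(mid, count)) +
    geom_col(fill = "grey40") +
    scale_y_log10() +
    geom_vline(xintercept = an$depth_threshold_m, linetype = "dashed") +
    labs(x = "depth of larva-day record (m)", y = "records (log scale)",
         title = "Vertical distribution of larva-day records"))

rd <- data.frame(days_inside = cap$days_inside, dist = dist_km)
ggsave("results/figures/residence_distance.png", width = 6, height = 4.5,
  plot = ggplot(rd, aes(days_inside, dist)) +
    geom_bin2d(bins = 30) +
    scale_fill_viridis_c(trans = "log10") +
    labs(x = "days inside the eddy", y = "distance from origin (km)",
         title = sprintf("Residence vs dispersal distance (r = %.2f)", r)))

dens_df <- expand.grid(lon = grid$lon, lat = grid$lat)
dens_df$count <- as.vector(dens)
coast_df <- as.data.frame(default_coastline())
ggsave("results/figures/density_map.png", width = 7, height = 5, plot =
  ggplot(subset(dens_df, count > 0), aes(lon, lat)) +
    geom_tile(aes(fill = count)) +
    scale_fill_viridis_c(trans = "log10") +
    geom_path(data = coast_df, aes(lon, lat), colour = "grey30") +
    coord_quickmap() +
    labs(title = "Larva-day density over the 30-day run",
         fill = "larva-days"))

message(sprintf(
  paste0("day-10 inside %.1f%%, day-16 outside %.1f%%, day-30 inside ",
         "%.1f%%; r = %.2f; deep records %.2f%%; cold (day %d) %.2f%%; ",
         "coastal arrivals %d; furthest larva %.0f km"),
  cap$trapped_pct[an$capture_day], 100 - cap$trapped_pct[an$outside_day],
  cap$trapped_pct[traj$t_days], r, depth$deep_fraction_pct, an$cold_day,
  cold$pct, coast$count, max(dist_km, na.rm = TRUE)))
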