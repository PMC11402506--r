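# Shared fixture builders: everything is generated in code at test time.

mk_deployment <- function(id = "bird1", nucleus = "Arribes", sex = "F",
                          nest_lon = -6.5, nest_lat = 41.3,
                          tagging_date = as.Date("2020-07-10"),
                          transmitter_model = "solar-GSM-30g") {
  data.frame(individual_id = id, sex = sex, nucleus = nucleus,
             nest_lon = nest_lon, nest_lat = nest_lat,
             tagging_date = tagging_date,
             transmitter_model = transmitter_model,
             sibling_group = NA_character_, stringsAsFactors = FALSE)
}

t_seq <- function(n, by_min = 30, start = "2020-07-10 00:00:00") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1L) * by_min * 60
}

mk_fixes <- function(timestamp, lon, lat, hdop = NA_real_,
                     vdop = NA_real_, battery_v = NA_real_,
                     activity = NA_real_) {
  data.frame(timestamp = timestamp, lon = lon, lat = lat, hdop = hdop,
             vdop = vdop, battery_v = battery_v, activity = activity)
}

mk_track <- function(fixes, deployment = mk_deployment()) {
  vt_track(fixes, deployment)
}

# A track heading due south from the nest through given latitudes at the
# nest longitude (one fix per element).
mk_lat_track <- function(lats, lon = -5.65, by_min = 30,
                         deployment = mk_deployment(nest_lon = lon,
                                                    nest_lat = lats[1])) {
  mk_track(mk_fixes(t_seq(length(lats), by_min), rep(lon, length(lats)),
                    lats), deployment)
}

# Place a point at a given distance (km) and bearing (deg, clockwise
# from north) from a reference, via the equal-area plane.
offset_point <- function(lon, lat, dist_km, bearing_deg = 0) {
  b <- bearing_deg * pi / 180
  unproject_laea(dist_km * sin(b), dist_km * cos(b), c(lon, lat))
}

# Write a cohort's fixes/deployments to temp CSVs; returns the paths.
write_temp_movebank <- function(tracks) {
  fx <- tempfile(fileext = ".csv")
  dp <- tempfile(fileext = ".csv")
  write_movebank(tracks, fx, dp)
  c(fx, dp)
}

# A small, fast simulation setup used across test files.
small_sim_config <- function(...) {
  sim_config(
    nuclei = data.frame(nucleus = c("Arribes", "Galicia"), n = c(4L, 2L),
                        nest_lon = c(-6.55, -7.30),
                        nest_lat = c(41.25, 42.10),
                        stringsAsFactors = FALSE),
    n_non_migrants = 1L, obs_days = 420, ...)
}
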