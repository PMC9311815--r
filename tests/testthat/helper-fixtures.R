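# shared fixture builders: everything is generated in code, no stored data

HOME_LL <- c(lat = 55.5, lon = 10.5)

# trajectory from planar offsets (metres, home at origin), UTC times
traj_local <- function(t_s, x, y, cat_id = "test", loc_err_sd = 13.1,
                       t0 = as.POSIXct("2021-08-02 00:00:00", tz = "UTC")) {
  ll <- from_local_xy(x, y, HOME_LL)
  trajectory(cat_id, t0 + t_s, ll$lat, ll$lon, loc_err_sd, home = HOME_LL)
}

# planar track (as consumed by the BBKDE layer) from a trajectory-free path
planar_track <- function(t_s, x, y, loc_err_sd = 13.1,
                         t0 = as.POSIXct("2021-08-02 00:00:00", tz = "UTC")) {
  data.frame(time = t0 + t_s, x = x, y = y, loc_err_sd = loc_err_sd)
}

# minimal GPX 1.1 document for reader tests
write_gpx <- function(path, time, lat, lon) {
  pts <- sprintf(
    '  <trkpt lat="%.8f" lon="%.8f"><time>%s</time></trkpt>',
    lat, lon, format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<gpx version="1.1" creator="test" xmlns="http://www.topografix.com/GPX/1/1">',
               "<trk><trkseg>", pts, "</trkseg></trk>", "</gpx>"), path)
  path
}

# random jittery but legal track for cleaning property tests
random_track <- function(n = 50, seed = 1) {
  set.seed(seed)
  t_s <- cumsum(c(0, sample(60:600, n - 1, TRUE)))
  x <- cumsum(rnorm(n, 0, 30))
  y <- cumsum(rnorm(n, 0, 30))
  traj_local(t_s, x, y, cat_id = paste0("rnd", seed))
}

# default movement parameters for direct simulate_cat_day calls
day_pars <- function(sigma = 55, mean_exc = 5000, mean_home = 18000,
                     speed = 0.17) {
  list(mean_home_dwell_s = mean_home, mean_excursion_s = mean_exc,
       sigma_m = sigma, attractor_dist_m = 1.5 * sigma, speed_ms = speed,
       transit_speed_ms = 0.6, leg_s = 60, turning_sd_rad = 20 * pi / 180,
       home_jitter_sd_m = 3)
}

DAY0 <- as.numeric(as.POSIXct("2021-08-02 00:00:00", tz = "UTC"))
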