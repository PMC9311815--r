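#' @name synthetic_cats
#' @title Synthetic cohorts with known ground truth
#' @description
#' Generates cats, covariates, municipality rainfall and GPS trajectories
#' whose true per-day away fraction and path length are known exactly, so
#' every pipeline stage can be validated without field data.
#'
#' The movement model alternates home dwells (stationary at a jittered
#' point near the anchor) with excursions: a transit to an attractor drawn
#' around the home, a slow heading-persistent meander pulled back towards
#' the attractor, and a straight return. The path is piecewise linear, so
#' true path length and true time outside the 50 m home disc are computed
#' exactly (the 1 s grid limit). The device emulates an
#' accelerometer-driven tracker: fixes every 2-10 min while moving, every
#' 60 min while stationary, isotropic Gaussian location error, and optional
#' blunder fixes (cell-tower glitches emitted as a burst fix 30-90 s after
#' a scheduled fix, displaced 0.5-2 km) to exercise the speed filter.
NULL

#' Simulator configuration
#'
#' Defaults describe a cohort like the field study: 97 cats tracked for 7
#' calendar days (partial first and last day), covariate frequencies
#' matching the study population, ~13 m GPS error, and effect structure
#' with older cats less active, nature access increasing roaming and
#' rainfall reducing movement.
#'
#' @param n_cats Number of animals (default 97).
#' @param days Calendar days tracked per animal (default 7).
#' @param seed Integer seed; recorded in the output.
#' @param start_date First tracking date.
#' @param ... Overrides for any element of the default config (`covariate_w`,
#'   `effects`, `movement`, `device`, `rainfall`, `n_municipalities`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cats = 97, days = 7, seed = 1L,
                       start_date = as.Date("2021-08-02"), ...) {
  cfg <- list(
    n_cats = n_cats, days = days, seed = as.integer(seed),
    start_date = start_date,
    n_municipalities = 12L,
    covariate_w = list(   # cohort frequencies
      sex = c("intact male" = 4, "neutered male" = 45,
              "intact female" = 3, "neutered female" = 45),
      age_group = c("1-3" = 32, "4-7" = 32, "8-16" = 33),
      breed = c("domestic shorthair" = 64, "purebred" = 15,
                "mixed/unknown" = 18),
      food_access = c("ad libitum" = 79, "restricted" = 18),
      land_use = c("rural" = 31, "suburban/cottage" = 54,
                   "urban/industry" = 12),
      busy_road = c("yes" = 46, "no" = 51),
      nature_access = c("yes" = 81, "no" = 16)),
    effects = list(
      # multiplies the mean excursion-bout duration (drives time away)
      away_mult = list(
        sex = c("intact male" = 1.5, "neutered male" = 1,
                "intact female" = 0.95, "neutered female" = 0.95),
        age_group = c("1-3" = 1.05, "4-7" = 1, "8-16" = 0.55),
        nature_access = c("yes" = 1, "no" = 0.6)),
      # multiplies meander speed (drives distance given time away)
      speed_mult = list(
        breed = c("domestic shorthair" = 0.88, "purebred" = 1.15,
                  "mixed/unknown" = 1)),
      # multiplies the excursion range scale sigma (drives home range)
      range_mult = list(
        sex = c("intact male" = 1.8, "neutered male" = 1,
                "intact female" = 0.85, "neutered female" = 0.95),
        age_group = c("1-3" = 1.25, "4-7" = 1, "8-16" = 0.7),
        nature_access = c("yes" = 1.1, "no" = 0.7),
        land_use = c("rural" = 1.2, "suburban/cottage" = 1,
                     "urban/industry" = 0.85)),
      rainfall_log_slope = -0.02),    # per mm, on excursion duration & speed
    movement = list(
      mean_home_dwell_s = 18000, mean_excursion_s = 5000,
      sigma_base_m = 55,           # per-axis range scale
      attractor_dist_mult = 1.5,   # attractor distance ~ mult * sigma
      speed_ms = 0.17,             # meander speed
      transit_speed_ms = 0.6,
      leg_s = 60, turning_sd_deg = 20,
      home_jitter_sd_m = 3),
    device = list(
      moving_interval_s = c(120, 600), stationary_interval_s = 3600,
      speed_threshold_ms = 0.05, loc_err_sd = 13.1,
      blunder_rate_per_day = 0.25, blunder_dist_m = c(500, 2000),
      blunder_lag_s = c(20, 45), wake_lag_s = c(5, 30)),
    rainfall = list(p_wet = 0.45, shape = 1.2, scale = 8))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "sim_config")
}

mult_for <- function(row, spec) {
  m <- 1
  for (v in names(spec)) m <- m * unname(spec[[v]][as.character(row[[v]])])
  m
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Simulate one cat-day of movement
#'
#' Returns the piecewise-linear true path and exact per-day truth for a
#' single animal-day, in the local planar frame (metres, home at origin).
#'
#' @param day_start_s,day_end_s Absolute start/end of the tracked window
#'   (seconds, e.g. POSIXct numeric).
#' @param pars List of movement parameters for this animal-day:
#'   `mean_home_dwell_s`, `mean_excursion_s`, `sigma_m`, `attractor_dist_m`,
#'   `speed_ms`, `transit_speed_ms`, `leg_s`, `turning_sd_rad`,
#'   `home_jitter_sd_m`.
#' @return List `waypoints` (data.frame `t, x, y`) and `truth`
#'   (`away_s`, `path_m`, `tracked_s`, each computed exactly from the
#'   path; away uses the 50 m home disc).
#' @export
simulate_cat_day <- function(day_start_s, day_end_s, pars) {
  t <- day_start_s
  jit <- function() rnorm(2L, 0, pars$home_jitter_sd_m)
  pos <- jit()
  ts <- t; xs <- pos[1L]; ys <- pos[2L]
  add <- function(t2, p2) {
    ts[length(ts) + 1L] <<- t2
    xs[length(xs) + 1L] <<- p2[1L]
    ys[length(ys) + 1L] <<- p2[2L]
  }
  while (t < day_end_s) {
    # home dwell
    dwell <- rexp(1L, 1 / pars$mean_home_dwell_s)
    t2 <- min(t + dwell, day_end_s)
    add(t2, pos)
    t <- t2
    if (t >= day_end_s) break
    # excursion: attractor around home
    phi <- runif(1L, 0, 2 * pi)
    A <- pars$attractor_dist_m * runif(1L, 0.7, 1.3) * c(cos(phi), sin(phi))
    exc_end <- t + rexp(1L, 1 / pars$mean_excursion_s)
    # outbound transit towards a start point near the attractor
    S <- A + rnorm(2L, 0, pars$sigma_m / 2)
    tt <- sqrt(sum((S - pos)^2)) / pars$transit_speed_ms
    if (t + tt >= day_end_s) {  # truncate transit at day end
      fr <- (day_end_s - t) / tt
      add(day_end_s, pos + fr * (S - pos))
      t <- day_end_s
      break
    }
    t <- t + tt; pos <- S; add(t, pos)
    heading <- runif(1L, 0, 2 * pi)
    step <- pars$speed_ms * pars$leg_s
    repeat {
      d_home <- sqrt(sum(pos^2))
      remain <- day_end_s - t
      if (t >= exc_end || remain <= d_home / pars$transit_speed_ms + pars$leg_s)
        break
      dA <- A - pos
      distA <- sqrt(sum(dA^2))
      # persistent heading inside the territory; steer home-ward only when
      # beyond the boundary, so paths stay locally straight (GPS chords then
      # recover path length)
      heading <- if (distA > 1.8 * pars$sigma_m)
        atan2(dA[2L], dA[1L]) + rnorm(1L, 0, pars$turning_sd_rad)
      else heading + rnorm(1L, 0, pars$turning_sd_rad)
      pos <- pos + step * c(cos(heading), sin(heading))
      t <- t + pars$leg_s
      add(t, pos)
    }
    # straight return home
    home_pt <- jit()
    tt <- sqrt(sum((pos - home_pt)^2)) / pars$transit_speed_ms
    if (t + tt >= day_end_s) {
      fr <- (day_end_s - t) / tt
      add(day_end_s, pos + fr * (home_pt - pos))
      t <- day_end_s
      break
    }
    t <- t + tt; pos <- home_pt; add(t, pos)
  }
  wp <- data.frame(t = ts, x = xs, y = ys)
  list(waypoints = wp, truth = path_truth(wp, radius = 50))
}

# exact time outside the radius-r home disc and exact path length of a
# piecewise-linear path
path_truth <- function(wp, radius = 50) {
  n <- nrow(wp)
  if (n < 2L) return(list(away_s = 0, path_m = 0, tracked_s = 0))
  x0 <- wp$x[-n]; y0 <- wp$y[-n]; x1 <- wp$x[-1L]; y1 <- wp$y[-1L]
  dt <- wp$t[-1L] - wp$t[-n]
  dx <- x1 - x0; dy <- y1 - y0
  seg <- sqrt(dx^2 + dy^2)
  away <- numeric(length(dt))
  a <- dx^2 + dy^2
  b <- 2 * (x0 * dx + y0 * dy)
  cc <- x0^2 + y0^2 - radius^2
  stationary <- a < 1e-12
  away[stationary] <- ifelse(cc[stationary] > 0, dt[stationary], 0)
  mv <- which(!stationary)
  disc <- b[mv]^2 - 4 * a[mv] * cc[mv]
  for (k in seq_along(mv)) {
    i <- mv[k]
    if (disc[k] <= 0) {              # never crosses the circle
      away[i] <- if (cc[i] > 0) dt[i] else 0
    } else {
      r1 <- (-b[i] - sqrt(disc[k])) / (2 * a[i])
      r2 <- (-b[i] + sqrt(disc[k])) / (2 * a[i])
      inside <- min(max(r1, 0), 1); outside <- min(max(r2, 0), 1)
      frac_in <- max(0, outside - inside)
      away[i] <- dt[i] * (1 - frac_in)
    }
  }
  list(away_s = sum(away), path_m = sum(seg), tracked_s = sum(dt))
}

#' Emit a GPS fix schedule from a true path
#'
#' Walks the device clock over the path: while the true speed exceeds
#' 0.05 m/s the next fix follows in 2-10 min (uniform), otherwise in 60
#' min. Isotropic Gaussian location error is added per axis; optional
#' blunder fixes are inserted 30-90 s after a randomly chosen scheduled
#' fix, displaced 0.5-2 km.
#'
#' @param wp Waypoint data.frame `t, x, y` (piecewise-linear path).
#' @param device Device parameter list (see [sim_config()]).
#' @return data.frame `t, x, y, blunder`.
#' @export
emit_fix_schedule <- function(wp, device) {
  t0 <- wp$t[1L]; t1 <- wp$t[nrow(wp)]
  seg_v <- c(with(wp, sqrt(diff(x)^2 + diff(y)^2) / pmax(diff(t), 1e-9)), 0)
  pos_at <- function(tt) {
    i <- findInterval(tt, wp$t, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(wp) - 1L)
    fr <- (tt - wp$t[i]) / max(wp$t[i + 1L] - wp$t[i], 1e-9)
    fr <- min(max(fr, 0), 1)
    c(wp$x[i] + fr * (wp$x[i + 1L] - wp$x[i]),
      wp$y[i] + fr * (wp$y[i + 1L] - wp$y[i]), seg_v[i])
  }
  # start times of moving segments, for the accelerometer wake-up rule
  moving <- seg_v[-length(seg_v)] > device$speed_threshold_ms
  move_starts <- wp$t[-nrow(wp)][moving & !c(FALSE, moving[-length(moving)])]
  ts <- numeric(0)
  t <- t0
  while (t <= t1) {
    ts <- c(ts, t)
    v <- pos_at(t)[3L]
    if (v > device$speed_threshold_ms) {
      t <- t + runif(1L, device$moving_interval_s[1L],
                     device$moving_interval_s[2L])
    } else {
      # inactive: hourly cadence, but the accelerometer wakes the device
      # when movement resumes and sampling restarts on the moving cadence
      t_next <- t + device$stationary_interval_s
      nxt <- move_starts[move_starts > t]
      if (length(nxt) && nxt[1L] < t_next)
        t_next <- min(t_next, nxt[1L] + runif(1L, device$wake_lag_s[1L],
                                              device$wake_lag_s[2L]))
      t <- t_next
    }
  }
  P <- t(vapply(ts, pos_at, numeric(3L)))
  fx <- data.frame(t = ts,
                   x = P[, 1L] + rnorm(length(ts), 0, device$loc_err_sd),
                   y = P[, 2L] + rnorm(length(ts), 0, device$loc_err_sd),
                   blunder = FALSE)
  nb <- rpois(1L, device$blunder_rate_per_day * (t1 - t0) / 86400)
  for (b in seq_len(nb)) {
    i <- sample.int(nrow(fx), 1L)
    tb <- fx$t[i] + runif(1L, device$blunder_lag_s[1L], device$blunder_lag_s[2L])
    if (tb > t1) next
    d <- runif(1L, device$blunder_dist_m[1L], device$blunder_dist_m[2L])
    phi <- runif(1L, 0, 2 * pi)
    pb <- pos_at(tb)
    fx <- rbind(fx, data.frame(t = tb, x = pb[1L] + d * cos(phi),
                               y = pb[2L] + d * sin(phi), blunder = TRUE))
  }
  fx[order(fx$t), , drop = FALSE]
}

#' Simulate a full cohort
#'
#' Draws covariates, municipality rainfall and per-day movement for every
#' animal; fully reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort`: `cats` (covariate table),
#'   `rainfall`, `trajectories` (named list of [trajectory()] objects),
#'   `truth` (list `daily`, `cats`), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  for (w in cfg$covariate_w)
    if (any(w < 0) || sum(w) <= 0) stop("validation error: invalid covariate weights")
  set.seed(cfg$seed)
  n <- cfg$n_cats
  ids <- sprintf("cat%03d", seq_len(n))
  cats <- data.frame(cat_id = ids)
  for (v in names(cfg$covariate_w)) {
    w <- cfg$covariate_w[[v]]
    cats[[v]] <- factor(sample(names(w), n, replace = TRUE, prob = w / sum(w)),
                        levels = cat_levels[[v]])
  }
  cats$municipality <- sprintf("mun%02d",
                               sample.int(cfg$n_municipalities, n, replace = TRUE))
  dates <- seq(cfg$start_date, by = "day", length.out = cfg$days)
  muns <- sort(unique(cats$municipality))
  rain <- expand.grid(municipality = muns, date = dates,
                      stringsAsFactors = FALSE)
  wet <- rbinom(nrow(rain), 1L, cfg$rainfall$p_wet)
  rain$rainfall_mm <- round(wet * rgamma(nrow(rain), cfg$rainfall$shape,
                                         scale = cfg$rainfall$scale), 1)
  tz <- cr_defaults()$tz
  day0 <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = tz))
  mv <- cfg$movement; dv <- cfg$device; ef <- cfg$effects
  trajectories <- vector("list", n); names(trajectories) <- ids
  daily_truth <- vector("list", n)
  sigma_cat <- numeric(n)
  for (ci in seq_len(n)) {
    row <- cats[ci, ]
    sigma <- mv$sigma_base_m * mult_for(row, ef$range_mult)
    sigma_cat[ci] <- sigma
    away_m <- mult_for(row, ef$away_mult)
    speed_m <- mult_for(row, ef$speed_mult)
    home_ll <- c(lat = runif(1L, 54.8, 57.5), lon = runif(1L, 8.2, 12.5))
    rain_cat <- rain[rain$municipality == row$municipality, ]
    rain_mm <- setNames(rain_cat$rainfall_mm, as.character(rain_cat$date))
    start_off <- runif(1L, 6, 12) * 3600    # partial first day
    end_off <- runif(1L, 12, 20) * 3600     # partial last day
    fx_all <- NULL
    tr_rows <- NULL
    for (di in seq_len(cfg$days)) {
      r_mm <- unname(rain_mm[as.character(dates[di])])
      rmult <- exp(ef$rainfall_log_slope * r_mm)
      pars <- list(mean_home_dwell_s = mv$mean_home_dwell_s,
                   mean_excursion_s = mv$mean_excursion_s * away_m * rmult,
                   sigma_m = sigma,
                   attractor_dist_m = mv$attractor_dist_mult * sigma,
                   speed_ms = mv$speed_ms * speed_m * rmult^0.5,
                   transit_speed_ms = mv$transit_speed_ms,
                   leg_s = mv$leg_s,
                   turning_sd_rad = mv$turning_sd_deg * pi / 180,
                   home_jitter_sd_m = mv$home_jitter_sd_m)
      t_a <- day0[di] + if (di == 1L) start_off else 0
      t_b <- day0[di] + if (di == cfg$days) end_off else 86400
      sim <- simulate_cat_day(t_a, t_b, pars)
      fx <- emit_fix_schedule(sim$waypoints, dv)
      fx_all <- rbind(fx_all, fx)
      tr_rows <- rbind(tr_rows, data.frame(
        cat_id = ids[ci], date = dates[di],
        true_away_frac = sim$truth$away_s / sim$truth$tracked_s,
        true_path_m = sim$truth$path_m,
        true_tracked_s = sim$truth$tracked_s,
        rainfall_mm = r_mm))
    }
    ll <- from_local_xy(fx_all$x, fx_all$y, home_ll)
    trajectories[[ci]] <- trajectory(ids[ci],
                                     as.POSIXct(fx_all$t, origin = "1970-01-01",
                                                tz = "UTC"),
                                     ll$lat, ll$lon, dv$loc_err_sd,
                                     home = home_ll)
    daily_truth[[ci]] <- tr_rows
  }
  truth_cats <- data.frame(cat_id = ids, range_sigma_m = sigma_cat,
                           true_range_ha = pi * qchisq(0.95, 2) *
                             sigma_cat^2 / 1e4)
  structure(list(cats = cats, rainfall = rain, trajectories = trajectories,
                 truth = list(daily = do.call(rbind, daily_truth),
                              cats = truth_cats),
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d cats x %d days (seed %d)\n",
              x$config$n_cats, x$config$days, x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk in the reader formats
#'
#' Emits per-cat CSV tracks, the covariate table, the rainfall table and
#' the daily truth table.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trajectories)
    write_track_csv(tr, file.path(dir, "tracks", paste0(tr$cat_id, ".csv")))
  write.csv(cohort$cats, file.path(dir, "cats.csv"), row.names = FALSE)
  write.csv(cohort$rainfall, file.path(dir, "rainfall.csv"), row.names = FALSE)
  write.csv(cohort$truth$daily, file.path(dir, "truth_daily.csv"),
            row.names = FALSE)
  write.csv(cohort$truth$cats, file.path(dir, "truth_cats.csv"),
            row.names = FALSE)
  invisible(dir)
}

## ---- reference stochastic-process tracks (for estimator validation) --------

#' Simulate a stationary Ornstein-Uhlenbeck planar track
#'
#' Exact AR1 discretisation per axis with stationary SD `sigma` and
#' relaxation time `tau`; Gaussian location error added. Such a track has a
#' closed-form 95% range area `pi * qchisq(.95, 2) * sigma^2`.
#'
#' @param n Number of fixes.
#' @param dt Fix interval (s).
#' @param sigma Per-axis stationary SD (m).
#' @param tau Relaxation time (s).
#' @param loc_err_sd Location error SD (m).
#' @return Planar track data.frame `time, x, y, loc_err_sd`.
#' @export
simulate_ou_track <- function(n, dt, sigma, tau, loc_err_sd = 5) {
  a <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - a^2)
  x <- numeric(n); y <- numeric(n)
  x[1L] <- rnorm(1L, 0, sigma); y[1L] <- rnorm(1L, 0, sigma)
  ex <- rnorm(n - 1L, 0, innov_sd); ey <- rnorm(n - 1L, 0, innov_sd)
  for (i in 2:n) {
    x[i] <- a * x[i - 1L] + ex[i - 1L]
    y[i] <- a * y[i - 1L] + ey[i - 1L]
  }
  data.frame(time = as.POSIXct(seq(0, by = dt, length.out = n),
                               origin = "1970-01-01", tz = "UTC"),
             x = x + rnorm(n, 0, loc_err_sd),
             y = y + rnorm(n, 0, loc_err_sd),
             loc_err_sd = loc_err_sd)
}

#' Simulate a planar Brownian-motion track
#'
#' Pure Brownian motion with diffusion coefficient `sigma1` (m s^-1/2) plus
#' Gaussian location error; the generating model of the bridge estimator,
#' used for `sigma1` parameter-recovery checks.
#'
#' @param n Number of fixes.
#' @param dt Fix interval (s).
#' @param sigma1 Diffusion coefficient (m s^-1/2).
#' @param loc_err_sd Location error SD (m).
#' @return Planar track data.frame `time, x, y, loc_err_sd`.
#' @export
simulate_bm_track <- function(n, dt, sigma1, loc_err_sd = 13.1) {
  sd_step <- sigma1 * sqrt(dt)
  x <- cumsum(c(0, rnorm(n - 1L, 0, sd_step)))
  y <- cumsum(c(0, rnorm(n - 1L, 0, sd_step)))
  data.frame(time = as.POSIXct(seq(0, by = dt, length.out = n),
                               origin = "1970-01-01", tz = "UTC"),
             x = x + rnorm(n, 0, loc_err_sd),
             y = y + rnorm(n, 0, loc_err_sd),
             loc_err_sd = loc_err_sd)
}
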