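#' @name movement_metrics
#' @title Time away from home base and daily distance moved
#' @description
#' The home base is the disc of radius 50 m around the home anchor; time
#' outside it counts as "away". Each inter-fix interval is attributed wholly
#' to the shared state when both endpoints agree and split 50/50 across a
#' transition; intervals are cut at local midnight so per-day totals are
#' exact. Daily distance sums great-circle segment lengths, each segment
#' assigned to the calendar day of its destination fix.
NULL

local_day <- function(time, tz = cr_defaults()$tz) as.Date(time, tz = tz)

# split the interval [t0, t1) at local midnights; returns data.frame
# (day, secs). Vectorised over intervals.
split_at_midnights <- function(t0, t1, tz = cr_defaults()$tz) {
  d0 <- local_day(t0, tz); d1 <- local_day(t1, tz)
  same <- d0 == d1
  out <- list(data.frame(day = d0[same],
                         secs = as.numeric(difftime(t1[same], t0[same], units = "secs"))))
  for (i in which(!same)) {
    days <- seq(d0[i], d1[i], by = "day")
    bounds <- as.POSIXct(paste(days[-1L], "00:00:00"), tz = tz)
    cuts <- c(t0[i], bounds, t1[i])
    secs <- as.numeric(diff(cuts), units = "secs")
    keep <- secs > 0
    out[[length(out) + 1L]] <- data.frame(day = days[keep], secs = secs[keep])
  }
  do.call(rbind, out)
}

#' Classify fixes as at home base or away
#'
#' @param traj A cleaned `cat_trajectory`.
#' @param radius Home-base radius in metres (default 50; boundary inclusive).
#' @return Character vector `"HOME"`/`"AWAY"`, one per fix.
#' @export
classify_home_away <- function(traj, radius = cr_defaults()$home_radius) {
  f <- traj$fixes
  d <- geodesic_m(traj$home[["lat"]], traj$home[["lon"]], f$lat, f$lon)
  # boundary inclusive; 1e-6 m slack absorbs projection round-trip noise
  ifelse(d <= radius + 1e-6, "HOME", "AWAY")
}

#' Per-day tracked and away time
#'
#' @param traj A cleaned `cat_trajectory`.
#' @param radius Home-base radius in metres.
#' @param tz Local timezone for day boundaries.
#' @return data.frame `cat_id, date, tracked_s, away_s`.
#' @export
time_away_per_day <- function(traj, radius = cr_defaults()$home_radius,
                              tz = cr_defaults()$tz) {
  st <- classify_home_away(traj, radius)
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2L) stop("insufficient data: need >= 2 fixes")
  t0 <- f$time[-n]; t1 <- f$time[-1L]
  w <- (as.integer(st[-n] == "AWAY") + as.integer(st[-1L] == "AWAY")) / 2
  # expand each interval across midnights, carrying its away weight
  d0 <- local_day(t0, tz); d1 <- local_day(t1, tz)
  same <- d0 == d1
  parts <- data.frame(day = d0[same],
                      secs = as.numeric(difftime(t1[same], t0[same], units = "secs")),
                      w = w[same])
  for (i in which(!same)) {
    sp <- split_at_midnights(t0[i], t1[i], tz)
    sp$w <- w[i]
    parts <- rbind(parts, sp)
  }
  agg <- aggregate(cbind(tracked_s = parts$secs, away_s = parts$secs * parts$w),
                   by = list(date = parts$day), FUN = sum)
  agg <- agg[order(agg$date), ]
  data.frame(cat_id = traj$cat_id, agg, row.names = NULL)
}

#' Per-day distance moved
#'
#' Sums great-circle distances over consecutive-fix segments; a segment
#' belongs to the calendar day of its destination fix.
#'
#' @inheritParams time_away_per_day
#' @return data.frame `cat_id, date, distance_m` (days with a single fix get
#'   0 m).
#' @export
daily_distance <- function(traj, tz = cr_defaults()$tz) {
  f <- traj$fixes
  n <- nrow(f)
  day <- local_day(f$time, tz)
  alldays <- seq(min(day), max(day), by = "day")
  dist <- setNames(numeric(length(alldays)), as.character(alldays))
  if (n >= 2L) {
    seg <- geodesic_m(f$lat[-n], f$lon[-n], f$lat[-1L], f$lon[-1L])
    dd <- as.character(day[-1L])
    s <- tapply(seg, dd, sum)
    dist[names(s)] <- s
  }
  data.frame(cat_id = traj$cat_id, date = alldays, distance_m = as.numeric(dist),
             row.names = NULL)
}

#' Drop first and last tracking days
#'
#' Animals are typically not tracked for the whole of their first and last
#' calendar days, so those days would understate daily totals.
#'
#' @param metrics Per-day records with a `date` column.
#' @return The records excluding the earliest and latest dates present.
#' @export
trim_first_last_days <- function(metrics) {
  days <- sort(unique(metrics$date))
  if (length(days) < 3L)
    stop("insufficient data: need >= 3 tracked days to trim first and last")
  out <- metrics[!(metrics$date %in% days[c(1L, length(days))]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag interrupted tracking
#'
#' TRUE when some interior calendar day between the first and last tracked
#' days contains no fixes at all (a collection interruption at day
#' granularity; a long gap within a day does not count).
#'
#' @inheritParams time_away_per_day
#' @return Logical flag.
#' @export
flag_interrupted <- function(traj, tz = cr_defaults()$tz) {
  day <- unique(local_day(traj$fixes$time, tz))
  alldays <- seq(min(day), max(day), by = "day")
  interior <- alldays[-c(1L, length(alldays))]
  length(interior) > 0L && !all(interior %in% day)
}

#' Pooled fraction of time away, boundary-adjusted for beta modelling
#'
#' `frac_raw = sum(away_s)/sum(tracked_s)`; because the beta likelihood is
#' undefined at 0 and 1, the value is mapped into (0,1) by the standard
#' Smithson-Verkuilen adjustment `(y*(n-1) + 0.5)/n`, with `n` the number of
#' animals in the cohort.
#'
#' @param metrics Per-day records with `tracked_s` and `away_s`.
#' @param n_cohort Cohort size used in the boundary adjustment.
#' @return List `frac_raw`, `frac_away` (adjusted), `mean_away_h_per_day`
#'   (24 h times the raw fraction, i.e. normalised by tracked time).
#' @export
percent_time_away <- function(metrics, n_cohort) {
  tr <- sum(metrics$tracked_s)
  if (tr <= 0) stop("tracked_s sums to zero")
  raw <- sum(metrics$away_s) / tr
  adj <- (raw * (n_cohort - 1) + 0.5) / n_cohort
  list(frac_raw = raw, frac_away = adj, mean_away_h_per_day = 24 * raw)
}

#' Per-day metrics table for one animal
#'
#' Joins time-away, distance and (optionally) rainfall into the canonical
#' per-day record, with the first/last-day trim applied after the join.
#'
#' @param traj A cleaned `cat_trajectory`.
#' @param municipality Municipality id used to look up rainfall.
#' @param rainfall Optional rainfall table from [read_rainfall()].
#' @param radius,tz See [time_away_per_day()].
#' @param trim Drop first and last tracking days (default `TRUE`).
#' @return data.frame `cat_id, date, tracked_s, away_s, distance_m[,
#'   rainfall_mm]`.
#' @export
daily_metrics <- function(traj, municipality = NULL, rainfall = NULL,
                          radius = cr_defaults()$home_radius,
                          tz = cr_defaults()$tz, trim = TRUE) {
  aw <- time_away_per_day(traj, radius, tz)
  di <- daily_distance(traj, tz)
  m <- merge(aw, di[, c("date", "distance_m")], by = "date", all = TRUE)
  m$cat_id <- traj$cat_id
  m$tracked_s[is.na(m$tracked_s)] <- 0
  m$away_s[is.na(m$away_s)] <- 0
  m$distance_m[is.na(m$distance_m)] <- 0
  m <- m[, c("cat_id", "date", "tracked_s", "away_s", "distance_m")]
  if (trim) m <- trim_first_last_days(m)
  if (!is.null(rainfall) && !is.null(municipality)) {
    r <- rainfall[rainfall$municipality == municipality,
                  c("date", "rainfall_mm"), drop = FALSE]
    m <- merge(m, r, by = "date", all.x = TRUE)
    m <- m[, c("cat_id", "date", "tracked_s", "away_s", "distance_m", "rainfall_mm")]
  }
  m[order(m$date), , drop = FALSE]
}
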