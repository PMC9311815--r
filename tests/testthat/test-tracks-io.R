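test_that("GPX and CSV readers return time-sorted trajectories", {
  tm <- as.POSIXct("2021-08-02 10:00:00", tz = "UTC") + c(0, 300, 600)
  gpx <- withr::local_tempfile(fileext = ".gpx")
  write_gpx(gpx, tm, c(55.5, 55.501, 55.502), c(10.5, 10.5, 10.5))
  tr <- read_track(gpx)
  expect_s3_class(tr, "cat_trajectory")
  expect_equal(n_fixes(tr), 3L)
  expect_true(all(diff(tr$fixes$time) > 0))

  # shuffled CSV rows come back sorted
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = format(tm[c(2, 3, 1)], "%Y-%m-%dT%H:%M:%SZ"),
                   lat = c(55.501, 55.502, 55.5), lon = 10.5)
  write.csv(df, csv, row.names = FALSE)
  tr2 <- read_track(csv)
  expect_equal(tr2$fixes$time, tm)
  expect_equal(tr2$fixes$lat, c(55.5, 55.501, 55.502))
})

test_that("reader errors: malformed timestamp is named, short files refused", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,lat,lon", "2021-08-02T10:00:00Z,55.5,10.5",
               "not-a-time,55.6,10.5", "2021-08-02T11:00:00Z,55.7,10.5"), csv)
  expect_error(read_track(csv), "row.*2")
  writeLines(c("time,lat,lon", "2021-08-02T10:00:00Z,55.5,10.5"), csv)
  expect_error(read_track(csv), "insufficient")
})

test_that("CSV round-trip preserves the fix sequence", {
  tr <- random_track(40, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, f)
  tr2 <- read_track(f, home = tr$home)
  expect_equal(tr2$fixes$time, tr$fixes$time)
  expect_equal(tr2$fixes$lat, tr$fixes$lat, tolerance = 1e-7)
  expect_equal(tr2$fixes$lon, tr$fixes$lon, tolerance = 1e-7)
})

test_that("anchor_home: first fix by default, override wins, validation", {
  tr <- traj_local(c(0, 60), c(120, 150), c(0, 0))
  # construction anchored at the supplied home, not the first fix
  expect_equal(unname(tr$home), unname(HOME_LL))
  tr2 <- anchor_home(tr, NULL)
  expect_equal(tr2$home[["lat"]], tr$fixes$lat[1])
  tr3 <- anchor_home(tr, c(56, 11))
  expect_equal(unname(tr3$home), c(56, 11))
  expect_error(anchor_home(tr, c(NA, 11)), "validation")
})

test_that("geodesic_m: identity, closed form, triangle inequality", {
  expect_identical(geodesic_m(55, 10, 55, 10), 0)
  # one degree of longitude on the equator = pi * R / 180
  expect_equal(geodesic_m(0, 0, 0, 1), pi * 6371000 / 180, tolerance = 1e-6)
  expect_equal(geodesic_m(c(55, 10), c(55.01, 10.01)),
               geodesic_m(c(55.01, 10.01), c(55, 10)))
  set.seed(42)
  for (i in 1:25) {
    p <- matrix(c(runif(3, 54, 57), runif(3, 8, 12)), ncol = 2)
    d12 <- geodesic_m(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- geodesic_m(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- geodesic_m(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-6)
  }
})

test_that("dedupe collapses shared timestamps, keeps first, is idempotent", {
  t0 <- as.POSIXct("2021-08-02 00:00:00", tz = "UTC")
  tr <- trajectory("d", t0 + c(0, 60, 60, 120), c(55, 55.1, 55.2, 55.3),
                   rep(10, 4), home = c(55, 10))
  dd <- dedupe(tr)
  expect_equal(n_fixes(dd), 3L)
  expect_equal(dd$fixes$lat[2], 55.1)  # first record wins
  expect_identical(dedupe(dd)$fixes, dd$fixes)
  tr2 <- random_track(20, seed = 5)
  expect_identical(dedupe(tr2)$fixes, tr2$fixes)
})

test_that("speed threshold selection follows the 5-10 m/s band rule", {
  # 4 segments at 7 m/s (420 m / 60 s), one at 12 m/s
  mk <- function(speeds) {
    x <- cumsum(c(0, speeds * 60))
    traj_local(seq(0, by = 60, length.out = length(x)), x, rep(0, length(x)))
  }
  expect_equal(select_speed_threshold(mk(c(7, 7, 7, 7, 12))), 10)
  expect_equal(select_speed_threshold(mk(rep(2, 6))), 5)
  # exactly min_band_count - 1 band segments -> 5
  expect_equal(select_speed_threshold(mk(c(7, 7, 1, 1))), 5)
  expect_equal(select_speed_threshold(mk(c(7, 7, 7, 1))), 10)
})

test_that("speed_filter removes blunders, is idempotent, guards degeneracy", {
  # 700 m jump in 60 s = 11.7 m/s: removed under both thresholds
  t_s <- seq(0, by = 60, length.out = 6)
  x <- c(0, 10, 20, 720, 30, 40)
  for (thr in c(5, 10)) {
    sf <- speed_filter(traj_local(t_s, x, rep(0, 6)), thr)
    expect_equal(sf$removed, 1L)
    expect_false(720 %in% round(to_local_xy(sf$traj)$x))
  }
  tr <- traj_local(t_s, seq(0, 500, length.out = 6), rep(0, 6))
  sf <- speed_filter(tr, 5)
  expect_equal(sf$removed, 0L)
  expect_identical(sf$traj$fixes, tr$fixes)
  sf2 <- speed_filter(sf$traj, 5)
  expect_identical(sf2$traj$fixes, sf$traj$fixes)
  # everything removed -> degenerate error
  fast <- traj_local(c(0, 10, 20), c(0, 500, 1000), c(0, 0, 0))
  expect_error(speed_filter(fast, 5), "degenerate")
})

test_that("local projection: centre, north displacement, inverse, accuracy", {
  tr <- traj_local(c(0, 60, 120), c(0, 0, 3000), c(0, 50, 4000))
  xy <- to_local_xy(tr)
  expect_equal(xy$x[1], 0, tolerance = 1e-6)
  expect_equal(xy$y[1], 0, tolerance = 1e-6)
  expect_equal(xy$x[2], 0, tolerance = 0.01)
  expect_equal(xy$y[2], 50, tolerance = 0.01)
  # round-trip near the origin
  ll <- from_local_xy(12.3, -45.6, HOME_LL)
  d <- geodesic_m(ll$lat, ll$lon,
                  from_local_xy(12.3, -45.6, HOME_LL)$lat,
                  from_local_xy(12.3, -45.6, HOME_LL)$lon)
  expect_lt(d, 1e-6)
  # pairwise planar norm vs geodesic within 0.1% up to 10 km
  set.seed(7)
  x <- runif(8, -5000, 5000); y <- runif(8, -5000, 5000)
  tr2 <- traj_local(seq(0, by = 600, length.out = 8), x, y)
  xy2 <- to_local_xy(tr2)
  f <- tr2$fixes
  for (i in 1:7) {
    g <- geodesic_m(f$lat[i], f$lon[i], f$lat[i + 1], f$lon[i + 1])
    p <- sqrt(diff(xy2$x[i:(i + 1)])^2 + diff(xy2$y[i:(i + 1)])^2)
    expect_equal(p, g, tolerance = 1e-3)
  }
  expect_error(to_local_xy(traj_local(c(0, 60), c(0, 6e4), c(0, 0))),
               "projection-validity")
})

test_that("cleaning invariants hold on random tracks", {
  for (seed in 1:5) {
    tr <- random_track(60, seed)
    cl <- clean_track(tr)
    v <- geodesic_m(head(cl$traj$fixes$lat, -1), head(cl$traj$fixes$lon, -1),
                    tail(cl$traj$fixes$lat, -1), tail(cl$traj$fixes$lon, -1)) /
      as.numeric(diff(cl$traj$fixes$time), units = "secs")
    expect_true(all(v <= cl$threshold + 1e-9))
    # surviving fixes unchanged
    key <- paste(format(cl$traj$fixes$time), cl$traj$fixes$lat,
                 cl$traj$fixes$lon)
    key0 <- paste(format(tr$fixes$time), tr$fixes$lat, tr$fixes$lon)
    expect_true(all(key %in% key0))
  }
})

test_that("metadata readers validate closed category sets", {
  df <- data.frame(cat_id = "c1", sex = "neutered male", age_group = "4-7",
                   breed = "purebred", food_access = "ad libitum",
                   land_use = "rural", busy_road = "no",
                   nature_access = "yes", municipality = "m1")
  rec <- read_cat_records(df)
  expect_s3_class(rec$sex, "factor")
  df$sex <- "tomcat"
  expect_error(read_cat_records(df), "invalid sex")
  rain <- data.frame(municipality = "m1", date = "2021-08-02",
                     rainfall_mm = 4.2)
  expect_s3_class(read_rainfall(rain)$date, "Date")
  expect_error(read_rainfall(transform(rain, rainfall_mm = -1)),
               "non-negative")
})
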