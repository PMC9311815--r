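#' @name bbkde_homerange
#' @title Brownian bridge kernel home ranges
#' @description
#' The utilization distribution (UD) is built from first principles as the
#' time-weighted mixture of Brownian bridges between consecutive fixes:
#' along the segment from `z_a` at time 0 to `z_b` at time `dt`, the
#' location at relative time `t` is bivariate normal with mean the linear
#' interpolation and variance `dt*t*(1-t)*sigma1^2 + (1-t)^2*delta^2 +
#' t^2*delta^2`, where `sigma1` is the Brownian diffusion coefficient
#' (m s^-1/2) and `delta` the GPS location-error SD (m). `sigma1` is
#' estimated by the classic leave-one-out likelihood over odd-indexed
#' interior fixes. Home-range area at a level (e.g. 95%) is the area of the
#' smallest set of raster cells holding that cumulative probability.
NULL

#' Bridge model parameters
#'
#' @param sigma1 Brownian motion diffusion coefficient, m s^-1/2.
#' @param loc_err_sd GPS location-error SD delta, metres.
#' @return An object of class `bridge_model`.
#' @export
bridge_model <- function(sigma1, loc_err_sd = cr_defaults()$loc_err_sd) {
  stopifnot(sigma1 >= 0, loc_err_sd > 0)
  structure(list(sigma1 = sigma1, loc_err_sd = loc_err_sd),
            class = "bridge_model")
}

# negative log-likelihood of sigma1 under the odd-point bridge construction
bb_negloglik <- function(sigma1, x, y, tsec, delta) {
  n <- length(x)
  i <- seq(2L, n - 1L, by = 2L)     # interior odd points (1-based even index)
  a <- i - 1L; b <- i + 1L
  dtt <- tsec[b] - tsec[a]
  tstar <- (tsec[i] - tsec[a]) / dtt
  mux <- x[a] + tstar * (x[b] - x[a])
  muy <- y[a] + tstar * (y[b] - y[a])
  # exact conditional variance of the noisy observation z_i given the noisy
  # endpoints: bridge variance + interpolated endpoint error + the observed
  # point's own error (without the last term sigma1 absorbs the GPS noise)
  s2 <- dtt * tstar * (1 - tstar) * sigma1^2 +
    (1 - tstar)^2 * delta^2 + tstar^2 * delta^2 + delta^2
  -sum(dnorm(x[i], mux, sqrt(s2), log = TRUE) +
         dnorm(y[i], muy, sqrt(s2), log = TRUE))
}

#' Estimate the Brownian diffusion coefficient sigma1
#'
#' Maximises the leave-one-out likelihood: each odd-indexed interior fix is
#' scored under the bridge spanned by its two neighbours. Bounded 1-D search
#' on `[0, sigma1_max]`.
#'
#' @param xy Planar track from [to_local_xy()] (columns `time`, `x`, `y`).
#' @param loc_err_sd Location-error SD delta (m); default taken from the
#'   track's `loc_err_sd` column mean, falling back to 13.1 m.
#' @param sigma1_max Upper search bound, m s^-1/2 (default 5); hitting it
#'   raises a warning.
#' @param tol Optimiser tolerance.
#' @return Estimated `sigma1` (m s^-1/2).
#' @export
estimate_sigma1 <- function(xy, loc_err_sd = NULL, sigma1_max = 5, tol = 1e-6) {
  if (nrow(xy) < 3L) stop("insufficient data: need >= 3 fixes to estimate sigma1")
  if (is.null(loc_err_sd))
    loc_err_sd <- if ("loc_err_sd" %in% names(xy)) mean(xy$loc_err_sd)
                  else cr_defaults()$loc_err_sd
  tsec <- as.numeric(xy$time) - as.numeric(xy$time[1L])
  if (any(diff(tsec) <= 0)) stop("times must be strictly increasing")
  opt <- optimize(bb_negloglik, c(0, sigma1_max), x = xy$x, y = xy$y,
                  tsec = tsec, delta = loc_err_sd, tol = tol)
  s1 <- opt$minimum
  if (s1 > sigma1_max * 0.999)
    warning("sigma1 estimate at the upper search bound (", sigma1_max, ")")
  # optimize() never evaluates exactly at the boundary; snap when flat at 0
  if (s1 < tol * 10 &&
      bb_negloglik(0, xy$x, xy$y, tsec, loc_err_sd) <=
        opt$objective + 1e-9) s1 <- 0
  s1
}

#' Compute the Brownian bridge utilization distribution on a raster
#'
#' Discretises `UD(z) = (1/T) * sum over segments of the time integral of
#' the bridge density` with `n_t` midpoint nodes per segment. Segments whose
#' time gap exceeds `gap_max_s` are excluded (bridges over tracking
#' interruptions fabricate corridors) and their time removed from `T`.
#' Masses are normalised to sum to one.
#'
#' @param xy Planar track (columns `time`, `x`, `y`).
#' @param model A [bridge_model()].
#' @param cell Cell size in metres (default 10, about the device error).
#' @param pad Grid padding beyond the fix bounding box (m); default three
#'   times the largest bridge SD.
#' @param n_t Integration nodes per segment (midpoint rule; default 10).
#' @param gap_max_s Maximum segment duration included (default 4 h).
#' @return `ud_grid` object: list `xg`, `yg` (cell-centre coordinates),
#'   `cell`, `masses` (matrix `length(xg)` x `length(yg)`).
#' @export
compute_ud <- function(xy, model, cell = 10, pad = NULL, n_t = 10L,
                       gap_max_s = 4 * 3600) {
  stopifnot(inherits(model, "bridge_model"), cell > 0, n_t >= 1L)
  s1 <- model$sigma1; delta <- model$loc_err_sd
  if (cell > 3 * delta)
    warning("resolution warning: cell size exceeds 3x location error SD")
  tsec <- as.numeric(xy$time) - as.numeric(xy$time[1L])
  n <- nrow(xy)
  dts <- diff(tsec)
  use <- which(dts > 0 & dts <= gap_max_s)
  if (length(use) == 0L) stop("no usable segments (all gaps exceed gap_max_s)")
  # largest bridge sd over used segments, for the default padding
  smax <- sqrt(max(dts[use]) * 0.25 * s1^2 + delta^2)
  if (is.null(pad)) pad <- 3 * smax
  xg <- seq(floor((min(xy$x) - pad) / cell) * cell,
            ceiling((max(xy$x) + pad) / cell) * cell, by = cell)
  yg <- seq(floor((min(xy$y) - pad) / cell) * cell,
            ceiling((max(xy$y) + pad) / cell) * cell, by = cell)
  M <- matrix(0, length(xg), length(yg))
  tmid <- (seq_len(n_t) - 0.5) / n_t
  for (k in use) {
    dt <- dts[k]
    mux <- xy$x[k] + tmid * (xy$x[k + 1L] - xy$x[k])
    muy <- xy$y[k] + tmid * (xy$y[k + 1L] - xy$y[k])
    s2 <- dt * tmid * (1 - tmid) * s1^2 +
      (1 - tmid)^2 * delta^2 + tmid^2 * delta^2
    s <- sqrt(s2)
    # separable Gaussian: accumulate crossprod of per-axis density matrices,
    # weighting each time node by the segment duration
    FX <- vapply(seq_len(n_t),
                 function(j) dnorm(xg, mux[j], s[j]), numeric(length(xg)))
    FY <- vapply(seq_len(n_t),
                 function(j) dnorm(yg, muy[j], s[j]), numeric(length(yg)))
    M <- M + (dt / n_t) * (FX %*% t(FY))
  }
  M <- M / sum(M)
  structure(list(xg = xg, yg = yg, cell = cell, masses = M),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid> %d x %d cells of %.1f m (mass sum %.6f)\n",
              length(x$xg), length(x$yg), x$cell, sum(x$masses)))
  invisible(x)
}

#' Isopleth (home-range) area of a utilization distribution
#'
#' Cells are ranked by probability mass; the area is the size of the
#' smallest cell set whose cumulative mass reaches `level`, converted to
#' hectares.
#'
#' @param ud A `ud_grid`.
#' @param level Cumulative probability in (0,1), e.g. 0.95.
#' @return Area in hectares.
#' @export
isopleth_area <- function(ud, level) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("validation error: level must be in (0,1)")
  m <- sort(as.numeric(ud$masses), decreasing = TRUE)
  k <- which(cumsum(m) >= level - 1e-12)[1L]
  k * ud$cell^2 / 1e4
}

#' Estimate home-range areas for one trajectory
#'
#' Composes projection, `sigma1` estimation, UD rasterisation and isopleth
#' extraction.
#'
#' @param traj A cleaned `cat_trajectory`.
#' @param levels Isopleth levels (default 50% and 95%).
#' @param cell,n_t,gap_max_s,sigma1_max See [compute_ud()] /
#'   [estimate_sigma1()].
#' @param loc_err_sd Location-error SD; default the track's mean per-fix SD.
#' @return List of class `homerange_result`: `cat_id`, `sigma1`, `areas_ha`
#'   (named by level), `cell`, `n_fixes`.
#' @export
home_range <- function(traj, levels = c(0.5, 0.95), cell = 10, n_t = 10L,
                       gap_max_s = 4 * 3600, sigma1_max = 5,
                       loc_err_sd = NULL) {
  xy <- to_local_xy(traj)
  if (is.null(loc_err_sd)) loc_err_sd <- mean(xy$loc_err_sd)
  s1 <- estimate_sigma1(xy, loc_err_sd, sigma1_max = sigma1_max)
  ud <- compute_ud(xy, bridge_model(s1, loc_err_sd), cell = cell, n_t = n_t,
                   gap_max_s = gap_max_s)
  areas <- vapply(levels, function(l) isopleth_area(ud, l), numeric(1))
  structure(list(cat_id = traj$cat_id, sigma1 = s1,
                 areas_ha = setNames(areas, paste0("area", round(100 * levels), "_ha")),
                 cell = cell, n_fixes = nrow(xy)),
            class = "homerange_result")
}

#' @export
print.homerange_result <- function(x, ...) {
  cat(sprintf("<homerange_result> %s: sigma1 = %.4f m s^-1/2; %s\n", x$cat_id,
              x$sigma1,
              paste(names(x$areas_ha), sprintf("%.2f", x$areas_ha),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Minimum convex polygon area (comparison utility)
#'
#' Convex hull of the `fraction` of fixes closest to the centroid; shoelace
#' area in hectares.
#'
#' @param xy Planar track (columns `x`, `y`).
#' @param fraction Fraction of fixes retained (default 1.0 = 100% MCP).
#' @return Area in hectares (0 with a warning for collinear points).
#' @export
mcp_area <- function(xy, fraction = 1.0) {
  stopifnot(fraction > 0, fraction <= 1)
  x <- xy$x; y <- xy$y
  if (length(x) < 3L) stop("insufficient data: need >= 3 fixes for an MCP")
  if (fraction < 1) {
    cx <- mean(x); cy <- mean(y)
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    keep <- order(d)[seq_len(max(3L, ceiling(fraction * length(x))))]
    x <- x[keep]; y <- y[keep]
  }
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) {
    warning("collinear fixes: MCP area is zero")
    return(0)
  }
  hx <- x[h]; hy <- y[h]
  a <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  a / 1e4
}

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' @param ud A `ud_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(ud$xg)),
               sprintf("nrows %d", length(ud$yg)),
               sprintf("xllcorner %.3f", min(ud$xg) - ud$cell / 2),
               sprintf("yllcorner %.3f", min(ud$yg) - ud$cell / 2),
               sprintf("cellsize %.3f", ud$cell),
               "NODATA_value -9999"), con)
  # ESRI rows run north -> south
  for (j in rev(seq_along(ud$yg)))
    writeLines(paste(formatC(ud$masses[, j], format = "e", digits = 6),
                     collapse = " "), con)
  invisible(path)
}

#' Isopleth outline as GeoJSON (WGS84)
#'
#' Emits the cells inside the isopleth as a MultiPolygon of cell squares,
#' unprojected through the inverse local projection. Intended for quick
#' inspection in GIS tools, not cartography.
#'
#' @param ud A `ud_grid`.
#' @param level Isopleth level in (0,1).
#' @param home Named `c(lat, lon)` anchor used by the projection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isopleth_geojson <- function(ud, level, home, path) {
  m <- as.numeric(ud$masses)
  o <- order(m, decreasing = TRUE)
  k <- which(cumsum(m[o]) >= level - 1e-12)[1L]
  idx <- o[seq_len(k)]
  ij <- arrayInd(idx, dim(ud$masses))
  half <- ud$cell / 2
  polys <- apply(ij, 1L, function(rc) {
    cx <- ud$xg[rc[1L]]; cy <- ud$yg[rc[2L]]
    xs <- cx + c(-half, half, half, -half, -half)
    ys <- cy + c(-half, -half, half, half, -half)
    ll <- from_local_xy(xs, ys, home)
    sprintf("[[%s]]", paste(sprintf("[%.8f,%.8f]", ll$lon, ll$lat),
                            collapse = ","))
  })
  json <- sprintf(paste0(
    '{"type":"Feature","properties":{"level":%g},',
    '"geometry":{"type":"MultiPolygon","coordinates":[%s]}}'),
    level, paste(polys, collapse = ","))
  writeLines(json, path)
  invisible(path)
}
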