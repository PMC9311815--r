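#' @name cli_pipeline
#' @title End-to-end pipeline and command-line entry point
#' @description
#' Orchestrates simulate -> clean -> metrics -> homerange -> models ->
#' report with a single config, a structured exclusion log and CSV report
#' tables shaped like the study's result tables (final-model coefficient
#' tables, the rainfall prediction curve, and stratified home-range
#' descriptives).
NULL

#' Default run configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Seed used by the simulate stage (and any seeded Monte Carlo).
#' @param ... Overrides: `tracks_dir`, `cats_csv`, `rainfall_csv`,
#'   `n_cats`, `days`, `home_radius`, `min_band_count`, `cell`,
#'   `gap_max_s`, `alpha_away`, `alpha_distance`, `alpha_homerange`,
#'   `outlier_ha`, `boxcox_mode`, `log_base`, `tz`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "catrange_run", seed = 1L, ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              tracks_dir = NULL, cats_csv = NULL, rainfall_csv = NULL,
              n_cats = 97L, days = 7L,
              home_radius = 50, min_band_count = 3L,
              cell = 10, gap_max_s = 4 * 3600,
              alpha_away = 0.05, alpha_distance = 0.05,
              alpha_homerange = 0.10,
              outlier_ha = 90, boxcox_mode = "power", log_base = 10,
              tz = cr_defaults()$tz)
  modifyList(cfg, list(...), keep.null = TRUE)
}

#' Read a run configuration from a key = value file
#'
#' Plain-text config: one `key = value` per line, `#` comments allowed;
#' numeric-looking values are converted. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("config error: malformed line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  base <- run_config()
  unknown <- setdiff(keys, names(base))
  if (length(unknown)) stop("config error: unknown key(s): ",
                            paste(unknown, collapse = ", "))
  out <- base
  for (i in seq_along(keys)) {
    v <- vals[i]
    num <- suppressWarnings(as.numeric(v))
    out[[keys[i]]] <- if (!is.na(num)) num else v
  }
  out$seed <- as.integer(out$seed)
  out
}

# simple polynomial rolling hash for config stamping (no external digest
# dependency; stays inside double-precision integer range)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# keep candidate terms (in priority order) only while the design retains
# at least `min_extra` residual degrees of freedom; small pilot cohorts
# cannot support the full covariate set
capacity_terms <- function(data, terms, min_extra = 3L) {
  d <- droplevels(data)
  p <- 1L
  kept <- character()
  for (tm in terms) {
    add <- if (is.numeric(d[[tm]])) 1L else max(nlevels(as.factor(d[[tm]])) - 1L, 1L)
    if (p + add + min_extra > nrow(d)) break
    p <- p + add
    kept <- c(kept, tm)
  }
  kept
}

pipe_log <- function(state, cat_id, stage, reason) {
  state$log <- rbind(state$log,
                     data.frame(cat_id = cat_id, stage = stage,
                                reason = reason))
  state
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order. All artifacts are
#' written under `cfg$out_dir`; `manifest.txt` records the config hash,
#' seed and artifact list, and `exclusions.csv` one machine-readable record
#' per dropped animal.
#'
#' @param cfg A [run_config()].
#' @param stages Subset of
#'   `c("simulate","clean","metrics","homerange","models","report")`
#'   (default all).
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`cohort`, `tracks`, `metrics`, `summaries`, `homeranges`, `models`).
#' @export
run_pipeline <- function(cfg = run_config(),
                         stages = c("simulate", "clean", "metrics",
                                    "homerange", "models", "report")) {
  order_all <- c("simulate", "clean", "metrics", "homerange", "models",
                 "report")
  stages <- order_all[order_all %in% stages]
  if (!length(stages)) stop("config error: no valid stages requested")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- list(log = data.frame(cat_id = character(), stage = character(),
                              reason = character()),
             artifacts = character())
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write.csv(df, p, row.names = FALSE)
    st$artifacts <<- c(st$artifacts, name)
    p
  }

  if ("simulate" %in% stages) {
    st$cohort <- simulate_cohort(sim_config(n_cats = cfg$n_cats,
                                            days = cfg$days,
                                            seed = cfg$seed))
    simdir <- file.path(cfg$out_dir, "sim")
    write_cohort(st$cohort, simdir)
    cfg$tracks_dir <- file.path(simdir, "tracks")
    cfg$cats_csv <- file.path(simdir, "cats.csv")
    cfg$rainfall_csv <- file.path(simdir, "rainfall.csv")
  }

  if (any(c("clean", "metrics", "homerange", "models", "report") %in% stages)) {
    if (is.null(cfg$tracks_dir) || !dir.exists(cfg$tracks_dir))
      stop("data error: tracks_dir missing (run the simulate stage or point ",
           "tracks_dir at GPX/CSV files)")
    st$cats <- read_cat_records(cfg$cats_csv)
    st$rain <- read_rainfall(cfg$rainfall_csv)
  }

  if ("clean" %in% stages) {
    files <- list.files(cfg$tracks_dir, pattern = "\\.(csv|gpx)$",
                        full.names = TRUE)
    if (!length(files)) stop("data error: no track files in ", cfg$tracks_dir)
    st$tracks <- list()
    clean_rows <- NULL
    for (f in files) {
      tr <- read_track(f)
      cl <- tryCatch(clean_track(tr, cfg$min_band_count),
                     error = function(e)
                       stop("data error in stage clean, cat ", tr$cat_id, ": ",
                            conditionMessage(e)))
      st$tracks[[tr$cat_id]] <- cl$traj
      clean_rows <- rbind(clean_rows,
                          data.frame(cat_id = tr$cat_id,
                                     threshold_ms = cl$threshold,
                                     removed = cl$removed))
    }
    emit(clean_rows, "cleaning.csv")
  }

  if ("metrics" %in% stages) {
    if (is.null(st$tracks)) stop("config error: metrics requires the clean stage")
    met <- NULL; summ <- NULL
    n_cohort <- length(st$tracks)
    for (tr in st$tracks) {
      mun <- st$cats$municipality[match(tr$cat_id, st$cats$cat_id)]
      m <- tryCatch(daily_metrics(tr, mun, st$rain, radius = cfg$home_radius,
                                  tz = cfg$tz),
                    error = function(e)
                      stop("data error in stage metrics, cat ", tr$cat_id,
                           ": ", conditionMessage(e)))
      met <- rbind(met, m)
      pa <- percent_time_away(m, n_cohort)
      summ <- rbind(summ,
                    data.frame(cat_id = tr$cat_id,
                               mean_away_h_per_day = pa$mean_away_h_per_day,
                               frac_away = pa$frac_away,
                               total_days = nrow(m),
                               mean_daily_distance_m = mean(m$distance_m),
                               interrupted = flag_interrupted(tr, cfg$tz)))
    }
    st$metrics <- met
    st$summaries <- summ
    emit(met, "daily_metrics.csv")
    emit(summ, "cat_summaries.csv")
  }

  if ("homerange" %in% stages) {
    if (is.null(st$tracks)) stop("config error: homerange requires the clean stage")
    hr <- NULL
    for (tr in st$tracks) {
      h <- tryCatch(home_range(tr, cell = cfg$cell, gap_max_s = cfg$gap_max_s),
                    error = function(e)
                      stop("model error in stage homerange, cat ", tr$cat_id,
                           ": ", conditionMessage(e)))
      hr <- rbind(hr, data.frame(cat_id = h$cat_id, sigma1 = h$sigma1,
                                 area50_ha = h$areas_ha[["area50_ha"]],
                                 area95_ha = h$areas_ha[["area95_ha"]]))
    }
    st$homeranges <- hr
    emit(hr, "homerange.csv")
  }

  if ("models" %in% stages) {
    if (is.null(st$summaries)) stop("config error: models requires the metrics stage")
    covs <- c("sex", "age_group", "breed", "food_access", "land_use",
              "busy_road", "nature_access")
    scr <- association_screen(st$cats[covs], alpha = 0.05,
                              sim_seed = cfg$seed)
    terms0 <- setdiff(covs, scr$exclude)
    emit(scr$pairs, "association_screen.csv")
    st$models <- list(screen = scr)

    # time-away beta regression (per-cat fractions)
    d_away <- merge(st$summaries, st$cats, by = "cat_id")
    terms_cat <- capacity_terms(d_away, terms0)
    bfit <- tryCatch(
      backward_eliminate(d_away, terms_cat, cfg$alpha_away,
                         make_fitter("beta", "frac_away")),
      error = function(e) stop("model error in stage models (beta): ",
                               conditionMessage(e)))
    st$models$away <- bfit
    emit(coef_table(bfit$fit), "table_away_model.csv")

    # daily-distance AR1 mixed model
    d_day <- merge(st$metrics, st$cats, by = "cat_id")
    interrupted <- st$summaries$cat_id[st$summaries$interrupted]
    for (cid in interrupted)
      st <- pipe_log(st, cid, "models", "interrupted_daily_collection")
    d_day <- d_day[!d_day$cat_id %in% interrupted & d_day$distance_m > 0, ]
    dterms0 <- c("rainfall_mm", terms0)
    lam <- boxcox_lambda(d_day, "distance_m", dterms0)
    dfit <- tryCatch(
      backward_eliminate(d_day, dterms0, cfg$alpha_distance,
                         make_fitter("lmm_ar1", "distance_m", lambda = lam,
                                     boxcox_mode = cfg$boxcox_mode)),
      error = function(e) stop("model error in stage models (lmm): ",
                               conditionMessage(e)))
    st$models$distance <- dfit
    st$models$lambda <- lam
    emit(coef_table(dfit$fit), "table_distance_model.csv")
    if ("rainfall_mm" %in% dfit$fit$terms) {
      pr <- predict_rainfall_curve(dfit$fit, c(0, 5, 10, 15, 25, 30, 35, 45))
      emit(pr, "table_rainfall_predictions.csv")
      st$models$rain_curve <- pr
    }

    # home-range log-linear model
    if (!is.null(st$homeranges)) {
      d_hr <- merge(st$homeranges, st$cats, by = "cat_id")
      hfit <- tryCatch(
        backward_eliminate(d_hr, capacity_terms(d_hr, terms0),
                           cfg$alpha_homerange,
                           make_fitter("lm", "area95_ha",
                                       outlier_ha = cfg$outlier_ha,
                                       log_base = cfg$log_base)),
        error = function(e) stop("model error in stage models (lm): ",
                                 conditionMessage(e)))
      n_out <- hfit$fit$n_excluded
      if (n_out > 0) {
        out_ids <- d_hr$cat_id[d_hr$area95_ha > cfg$outlier_ha]
        for (cid in out_ids)
          st <- pipe_log(st, cid, "models", "homerange_outlier_gt_90ha")
      }
      st$models$homerange <- hfit
      emit(coef_table(hfit$fit), "table_homerange_model.csv")
    }
  }

  if ("report" %in% stages) {
    if (!is.null(st$homeranges)) {
      d_hr <- merge(st$homeranges, st$cats, by = "cat_id")
      desc <- report_descriptives(d_hr$area95_ha,
                                  d_hr[c("sex", "age_group", "breed",
                                         "food_access", "land_use",
                                         "busy_road", "nature_access")])
      emit(desc, "table_homerange_descriptives.csv")
    }
    if (!is.null(st$summaries)) {
      desc_aw <- report_descriptives(st$summaries$mean_away_h_per_day,
                                     data.frame(overall = "all"))
      emit(desc_aw, "table_away_descriptives.csv")
    }
  }

  emit(st$log, "exclusions.csv")
  writeLines(c(paste("config_hash:", config_hash(cfg)),
               paste("seed:", cfg$seed),
               paste("stages:", paste(stages, collapse = ",")),
               "artifacts:",
               paste(" -", st$artifacts)),
             file.path(cfg$out_dir, "manifest.txt"))
  invisible(st)
}

#' Stratified descriptive summary (report table)
#'
#' Per stratum of each grouping variable: n, min, quartiles (type-7 linear
#' interpolation), median, mean, max and SD, plus an overall row.
#'
#' @param values Numeric vector.
#' @param strata data.frame of grouping variables aligned with `values`.
#' @return data.frame `variable, level, n, min, q1, median, mean, q3, max,
#'   sd`.
#' @export
report_descriptives <- function(values, strata) {
  srow <- function(v, lev, x) {
    if (!length(x))
      return(data.frame(variable = v, level = lev, n = 0L, min = NA, q1 = NA,
                        median = NA, mean = NA, q3 = NA, max = NA, sd = NA))
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = v, level = lev, n = length(x), min = min(x),
               q1 = q[1L], median = q[2L], mean = mean(x), q3 = q[3L],
               max = max(x), sd = if (length(x) > 1L) sd(x) else NA_real_)
  }
  out <- srow("Overall", "-", values)
  for (v in names(strata)) {
    f <- as.factor(strata[[v]])
    for (lev in levels(f))
      out <- rbind(out, srow(v, lev, values[f == lev]))
  }
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' `catrange_cli(c("all", "--config", "run.cfg", "--seed", "7", "--out",
#' "run1"))`. Verbs: `simulate`, `clean`, `metrics`, `homerange`, `models`,
#' `report`, `all`; `--stages` may give a comma-separated subset. Returns
#' (rather than calls `quit` with) the exit code: 0 ok, 2 config error,
#' 3 data error, 4 model error.
#'
#' @param args Character vector of CLI arguments.
#' @return Integer exit code, invisibly.
#' @export
catrange_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: catrange <simulate|clean|metrics|homerange|models",
                 "|report|all> [--config FILE] [--seed N] [--out DIR]",
                 "[--stages a,b,c]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  verb <- args[1L]; rest <- args[-1L]
  opt <- list(config = NULL, seed = NULL, out = NULL, stages = NULL)
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest)) {
      message("config error: bad argument ", rest[i], "\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  all_stages <- c("simulate", "clean", "metrics", "homerange", "models",
                  "report")
  stages <- if (verb == "all") all_stages
            else if (verb %in% all_stages) all_stages[seq_len(match(verb, all_stages))]
            else { message("config error: unknown verb ", verb); return(invisible(2L)) }
  if (!is.null(opt$stages))
    stages <- intersect(all_stages, strsplit(opt$stages, ",")[[1L]])
  cfg <- tryCatch({
    c0 <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
    if (!is.null(opt$seed)) c0$seed <- as.integer(opt$seed)
    if (!is.null(opt$out)) c0$out_dir <- opt$out
    c0
  }, error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(cfg)) return(invisible(2L))
  res <- tryCatch({ run_pipeline(cfg, stages); 0L },
                  error = function(e) {
                    msg <- conditionMessage(e)
                    message(msg)
                    if (grepl("config error", msg)) 2L
                    else if (grepl("data error", msg)) 3L
                    else 4L
                  })
  invisible(res)
}
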