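## Synthetic herd generator with known ground truth.
##
## Emulates the statistical structure the analysis assumes: monthly test-day
## sampling with the first record on DIM 5-42 and ~30 +/- 3 day gaps, a fixed
## calendar alping season (15 May - 31 Aug, ~100 days), per-cow yield curves
## from the extended Wilmink family with Gaussian cow-level and residual
## noise (floored at 0), alp altitudes uniform on 1100-2600 m, and optional
## spatially smooth climate fields sampled by noisy stations.
##
## Calvings default to the 15th of the month so a calving-month cohort
## shares its ascent/return DIMs and the per-cohort hinge model is exactly
## the generating model; calving_day_jitter spreads the days to emulate real
## calendars.

#' Simulation configuration
#'
#' @param n_cows number of cows (one lactation each).
#' @param years calving years to draw from.
#' @param calving_month_weights named month-number -> probability map
#'   (default: autumn/winter calvings, September--February, as the QC rules
#'   retain).
#' @param calving_day,calving_day_jitter day-of-month and uniform jitter in
#'   days (0: all calvings of a month share the day).
#' @param parity_weights named parity -> probability map.
#' @param truth named list of curve parameters
#'   `a, b, c, d, f, g` (kg, kg, kg/day, kg/day, kg, kg/day) and `k`
#'   (1/day). For multi-group simulations pass `group_truth`, a list of such
#'   lists, plus `group_weights`.
#' @param group_truth,group_weights optional per-group truths and sampling
#'   probabilities; cows are assigned a group label `"g1"`, `"g2"`, ...
#' @param month_d optional named calving-month -> `d` map overriding
#'   `truth$d` per cohort (ignored when `group_truth` is given). The default
#'   grades `d` from -0.08 kg/day for September to -0.02 for February
#'   calvings: cows alped late in their cycle are hit harder by the alp
#'   than fresh ones, which is the seasonal pattern these herds show.
#'   Set `NULL` for a single `d` everywhere.
#' @param cow_sd named between-cow standard deviations (default on `a` and
#'   `d` only).
#' @param dry_off_kg cows stop being recorded once their cohort's noiseless
#'   curve falls below this daily yield (kg); emulates dry-off, which in
#'   practice ends a lactation long before the 500-DIM record window does.
#' @param dry_off_jitter_sd sd (days) of the cow-level dry-off jitter,
#'   drawn independently of the cow's yield so late-lactation curve points
#'   are not survivor-selected; capped at 3 sd.
#' @param resid_sd residual measurement noise, kg.
#' @param alping_start,alping_end `"mm-dd"` calendar alping season.
#' @param record_interval,record_jitter mean gap between test days (days)
#'   and its uniform integer jitter.
#' @param first_record_window DIM window of the first record.
#' @param max_dim last DIM records are taken at.
#' @param n_alps,alp_altitude_range,regions alp registry settings.
#' @param domain planar bounding box, m: `c(xmin, xmax, ymin, ymax)`.
#' @param climate `NULL` (skip climate generation) or a list of settings:
#'   `n_stations`, `station_noise` (sd of station error), `cell_size` (m),
#'   `seasonal_amp`, `lapse` (deg C / 100 m, negative).
#' @param seed integer seed; every source of randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cows = 500,
                       years = 2005:2009,
                       calving_month_weights = c(`9` = 0.25, `10` = 0.2, `11` = 0.1,
                                                 `12` = 0.1, `1` = 0.1, `2` = 0.25),
                       calving_day = 15, calving_day_jitter = 0,
                       parity_weights = c(`1` = 0.4, `2` = 0.25, `3` = 0.15,
                                          `4` = 0.1, `5` = 0.06, `6` = 0.04),
                       truth = list(a = 22, b = -8, c = -0.02, d = -0.08,
                                    f = 1.5, g = -0.04, k = 0.1),
                       group_truth = NULL, group_weights = NULL,
                       month_d = c(`9` = -0.08, `10` = -0.068, `11` = -0.056,
                                   `12` = -0.044, `1` = -0.032, `2` = -0.02),
                       cow_sd = c(a = 1.5, d = 0.003),
                       resid_sd = 1.5,
                       dry_off_kg = 3, dry_off_jitter_sd = 6,
                       alping_start = "05-15", alping_end = "08-31",
                       record_interval = 30, record_jitter = 3,
                       first_record_window = c(5, 42),
                       max_dim = 500,
                       n_alps = 25, alp_altitude_range = c(1100, 2600),
                       regions = c("Northern Alps", "Eastern Alps"),
                       domain = c(xmin = 2600000, xmax = 2750000,
                                  ymin = 1120000, ymax = 1220000),
                       climate = NULL,
                       seed = 1L) {
  w <- calving_month_weights / sum(calving_month_weights)
  stopifnot(all(cow_sd >= 0), resid_sd >= 0)
  if (!is.null(group_truth) && is.null(group_weights)) {
    group_weights <- rep(1 / length(group_truth), length(group_truth))
  }
  structure(list(n_cows = n_cows, years = years, calving_month_weights = w,
                 calving_day = calving_day, calving_day_jitter = calving_day_jitter,
                 parity_weights = parity_weights / sum(parity_weights),
                 truth = truth, group_truth = group_truth,
                 group_weights = group_weights, month_d = month_d,
                 cow_sd = cow_sd, resid_sd = resid_sd,
                 dry_off_kg = dry_off_kg, dry_off_jitter_sd = dry_off_jitter_sd,
                 alping_start = alping_start, alping_end = alping_end,
                 record_interval = record_interval, record_jitter = record_jitter,
                 first_record_window = first_record_window, max_dim = max_dim,
                 n_alps = n_alps, alp_altitude_range = alp_altitude_range,
                 regions = regions, domain = domain, climate = climate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# extended Wilmink curve value; t1/t2 vectors aligned with t
.truth_curve <- function(t, p, t1, t2) {
  p$a + p$b * exp(-p$k * t) + p$c * t +
    p$d * pmax(0, t - t1) +
    p$f * pmin(1, pmax(0, ceiling((t - t2) / 305))) +
    p$g * pmax(0, t - t2)
}

#' Simulate a herd dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @return a list with the herd tables (`records`, `lactations`, `cows`,
#'   `alps`), `climate` (`NULL` unless configured; otherwise `grids`,
#'   `stations` and the generating `fields` functions) and `truth`:
#'   the configured parameters, the per-cow parameter draws and group
#'   labels, per-cow `t1`/`t2`, and `expected_delta_d` for two-group runs.
#' @export
simulate_herd <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_cows

  months <- as.integer(sample(names(cfg$calving_month_weights), n, replace = TRUE,
                              prob = cfg$calving_month_weights))
  yrs <- cfg$years[sample.int(length(cfg$years), n, replace = TRUE)]
  day <- cfg$calving_day
  if (cfg$calving_day_jitter > 0) {
    day <- day + sample(seq(-cfg$calving_day_jitter, cfg$calving_day_jitter),
                        n, replace = TRUE)
  }
  calving <- as.Date(sprintf("%d-%02d-%02d", yrs, months, day))

  ## alping calendar: first season starting strictly after calving
  same_year <- as.Date(sprintf("%d-%s", yrs, cfg$alping_start))
  ascent <- data.table::fifelse(same_year > calving, same_year,
                                as.Date(sprintf("%d-%s", yrs + 1L, cfg$alping_start)))
  ret <- as.Date(sprintf("%d-%s", as.integer(format(ascent, "%Y")), cfg$alping_end))
  t1 <- as.integer(ascent - calving)
  t2 <- as.integer(ret - calving)

  ## groups and per-cow parameters
  if (!is.null(cfg$group_truth)) {
    gi <- sample(seq_along(cfg$group_truth), n, replace = TRUE,
                 prob = cfg$group_weights)
    group <- paste0("g", gi)
    truths <- cfg$group_truth
  } else {
    gi <- rep(1L, n)
    group <- rep("g1", n)
    truths <- list(cfg$truth)
  }
  par_names <- c("a", "b", "c", "d", "f", "g")
  pop_par <- sapply(par_names, function(p) {
    vapply(truths, function(tr) tr[[p]], numeric(1))[gi]
  })
  pop_par <- matrix(pop_par, nrow = n, dimnames = list(NULL, par_names))
  if (is.null(cfg$group_truth) && !is.null(cfg$month_d)) {
    hit <- match(as.character(months), names(cfg$month_d))
    pop_par[, "d"] <- ifelse(is.na(hit), pop_par[, "d"], cfg$month_d[hit])
  }
  cow_par <- pop_par
  for (p in names(cfg$cow_sd)) {
    cow_par[, p] <- cow_par[, p] + rnorm(n, 0, cfg$cow_sd[[p]])
  }
  k <- truths[[1]]$k

  ## dry-off: last recorded DIM is where the cow's cohort-level (noiseless,
  ## population-parameter) curve drops below dry_off_kg, plus an independent
  ## jitter; independence of the jitter from the cow's own yield keeps
  ## late-lactation averages free of survivor selection
  combo <- paste(t1, t2, round(pop_par[, "d"], 6), gi)
  dry_base <- rep(cfg$max_dim, n)
  for (cb in unique(combo)) {
    i1 <- which(combo == cb)[1]
    p <- as.list(pop_par[i1, ]); p$k <- k
    grid_t <- seq_len(cfg$max_dim)
    mu <- .truth_curve(grid_t, p, t1[i1], t2[i1])
    low <- which(mu < cfg$dry_off_kg & grid_t > 50)
    dry_base[combo == cb] <- if (length(low)) low[1] - 1L else cfg$max_dim
  }
  jit <- round(pmin(3 * cfg$dry_off_jitter_sd,
                    pmax(-3 * cfg$dry_off_jitter_sd,
                         rnorm(n, 0, cfg$dry_off_jitter_sd))))
  dry_off <- pmin(cfg$max_dim, dry_base + jit)

  ## alps
  dom <- cfg$domain
  alps <- data.frame(
    alp_id = sprintf("A%03d", seq_len(cfg$n_alps)),
    easting = runif(cfg$n_alps, dom["xmin"], dom["xmax"]),
    northing = runif(cfg$n_alps, dom["ymin"], dom["ymax"]),
    altitude_m = runif(cfg$n_alps, cfg$alp_altitude_range[1], cfg$alp_altitude_range[2]),
    region = sample(cfg$regions, cfg$n_alps, replace = TRUE),
    stringsAsFactors = FALSE)
  alp_of <- sample(alps$alp_id, n, replace = TRUE)

  ## cows and lactations
  parity <- as.integer(sample(names(cfg$parity_weights), n, replace = TRUE,
                              prob = cfg$parity_weights))
  age_first <- runif(n, 2.2, 3.5) * 365.25
  birth <- calving - round(age_first + (parity - 1) * 370)
  cow_id <- sprintf("C%05d", seq_len(n))
  cows <- data.frame(cow_id = cow_id, breed = "Braunvieh",
                     sire_breed = "Braunvieh", dam_breed = "Braunvieh",
                     birth_date = birth,
                     height_cm = round(rnorm(n, 141, 3), 1),
                     foot_angle = pmin(9L, pmax(1L, as.integer(round(rnorm(n, 5, 1.6))))),
                     stringsAsFactors = FALSE)
  insem_dim <- round(runif(n, 50, 120))
  insem <- calving + insem_dim
  lact_id <- sprintf("L%05d", seq_len(n))
  lactations <- data.frame(lactation_id = lact_id, cow_id = cow_id,
                           parity = parity, calving_date = calving,
                           insemination_dates = format(insem, "%Y-%m-%d"),
                           alp_id = alp_of,
                           next_calving_date = insem + 283,
                           stringsAsFactors = FALSE)

  ## test-day DIMs: monthly recording visits on a herd schedule whose phase
  ## is independent of the calving date (visit offset uniform over the
  ## interval), spaced record_interval +/- jitter; the first visit at
  ## DIM >= first_record_window[1] becomes the first record, which lands
  ## within the first_record_window automatically
  max_rec <- ceiling(cfg$max_dim / (cfg$record_interval - cfg$record_jitter)) + 2L
  offset0 <- sample(seq(0, cfg$record_interval - 1), n, replace = TRUE)
  gaps <- matrix(cfg$record_interval +
                   sample(seq(-cfg$record_jitter, cfg$record_jitter),
                          n * (max_rec - 1), replace = TRUE),
                 nrow = n)
  for (j in seq(2, ncol(gaps))) gaps[, j] <- gaps[, j] + gaps[, j - 1]
  dims <- cbind(offset0, offset0 + gaps)
  keep <- dims >= cfg$first_record_window[1] & dims <= pmin(cfg$max_dim, dry_off)
  ci <- rep(seq_len(n), ncol(dims))[keep]
  dim_ <- dims[keep]

  rd <- calving[ci] + dim_
  on_alp <- rd >= ascent[ci] & rd <= ret[ci]
  mu <- .truth_curve(dim_, list(a = cow_par[ci, "a"], b = cow_par[ci, "b"],
                                c = cow_par[ci, "c"], d = cow_par[ci, "d"],
                                f = cow_par[ci, "f"], g = cow_par[ci, "g"], k = k),
                     t1[ci], t2[ci])
  y <- pmax(0, mu + rnorm(length(mu), 0, cfg$resid_sd))
  records <- data.frame(cow_id = cow_id[ci], lactation_id = lact_id[ci],
                        record_date = rd, milk_kg = y,
                        fat_pct = round(rnorm(length(y), 4.0, 0.3), 2),
                        protein_pct = round(rnorm(length(y), 3.4, 0.2), 2),
                        scc = round(exp(rnorm(length(y), log(80), 0.5))),
                        site = ifelse(on_alp, "alp", "lowland"),
                        alp_id = ifelse(on_alp, alp_of[ci], NA_character_),
                        stringsAsFactors = FALSE)
  ord <- order(records$lactation_id, records$record_date)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  climate <- NULL
  if (!is.null(cfg$climate)) {
    date_range <- range(c(records$record_date[records$site == "alp"] - 31,
                          records$record_date[records$site == "alp"]))
    climate <- .simulate_climate(cfg, alps, date_range)
  }

  truth <- list(config = cfg, k = k,
                params = if (is.null(cfg$group_truth)) cfg$truth else cfg$group_truth,
                cow_params = data.frame(cow_id = cow_id, lactation_id = lact_id,
                                        group = group, cow_par,
                                        t1 = t1, t2 = t2, dry_off = dry_off,
                                        stringsAsFactors = FALSE))
  if (!is.null(cfg$group_truth) && length(cfg$group_truth) == 2) {
    truth$expected_delta_d <- cfg$group_truth[[1]]$d - cfg$group_truth[[2]]$d
  }
  list(records = records, lactations = lactations, cows = cows, alps = alps,
       climate = climate, truth = truth)
}

## smooth synthetic climate: deterministic fields of (x, y, elevation, doy),
## gridded at cell_size with a smooth reference elevation surface, plus noisy
## stations sampling the RH/wind fields.
.climate_fields <- function(lapse) {
  elev <- function(x, y) {
    1500 + 500 * sin(x / 40000) + 350 * cos(y / 30000)
  }
  t_max0 <- function(x, y, doy) {   # at sea level
    13 + 11 * sin(2 * pi * (doy - 105) / 365) + 1.5 * sin(x / 60000)
  }
  list(
    elev = elev,
    t_max = function(x, y, doy, e = elev(x, y)) t_max0(x, y, doy) + lapse * e / 100,
    t_mean = function(x, y, doy, e = elev(x, y)) t_max0(x, y, doy) - 6 + lapse * e / 100,
    rain = function(x, y, doy) pmax(4 + 2.5 * sin(2 * pi * doy / 365) +
                                      1.5 * cos(y / 45000), 0),
    rh = function(x, y, doy) pmin(pmax(72 + 8 * sin(y / 50000) +
                                         5 * sin(2 * pi * doy / 365), 0), 100),
    ws = function(x, y, doy) pmax(3 + 1.2 * sin(x / 35000) +
                                    0.8 * cos(2 * pi * doy / 365), 0)
  )
}

.simulate_climate <- function(cfg, alps, date_range) {
  cc <- cfg$climate
  n_st <- if (is.null(cc$n_stations)) 40L else cc$n_stations
  st_noise <- if (is.null(cc$station_noise)) 0.3 else cc$station_noise
  cell <- if (is.null(cc$cell_size)) 2000 else cc$cell_size
  lapse <- if (is.null(cc$lapse)) -0.45 else cc$lapse
  dom <- cfg$domain
  fields <- .climate_fields(lapse)

  xs <- seq(dom["xmin"] + cell / 2, dom["xmax"], by = cell)
  ys <- seq(dom["ymax"] - cell / 2, dom["ymin"], by = -cell)  # row 1 = north
  gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  ref_elev <- fields$elev(gx, gy)

  dates <- seq(date_range[1], date_range[2], by = "day")
  doys <- as.integer(format(dates, "%j"))
  grids <- list(t_max = list(), t_mean = list(), rain = list())
  for (i in seq_along(dates)) {
    key <- as.character(dates[i])
    grids$t_max[[key]] <- climate_grid("t_max", dates[i], dom["xmin"], dom["ymin"],
                                       cell, fields$t_max(gx, gy, doys[i], ref_elev),
                                       ref_elev)
    grids$t_mean[[key]] <- climate_grid("t_mean", dates[i], dom["xmin"], dom["ymin"],
                                        cell, fields$t_mean(gx, gy, doys[i], ref_elev),
                                        ref_elev)
    grids$rain[[key]] <- climate_grid("rain", dates[i], dom["xmin"], dom["ymin"],
                                      cell, fields$rain(gx, gy, doys[i]))
  }
  sx <- runif(n_st, dom["xmin"], dom["xmax"])
  sy <- runif(n_st, dom["ymin"], dom["ymax"])
  st <- expand.grid(si = seq_len(n_st), di = seq_along(dates),
                    variable = c("rh", "ws"), stringsAsFactors = FALSE)
  val <- ifelse(st$variable == "rh",
                fields$rh(sx[st$si], sy[st$si], doys[st$di]),
                fields$ws(sx[st$si], sy[st$si], doys[st$di]))
  stations <- data.frame(station_id = sprintf("S%03d", st$si),
                         easting = sx[st$si], northing = sy[st$si],
                         elevation_m = fields$elev(sx[st$si], sy[st$si]),
                         variable = st$variable,
                         date = as.character(dates[st$di]),
                         value = val + rnorm(nrow(st), 0, st_noise),
                         stringsAsFactors = FALSE)
  list(grids = grids, stations = stations, fields = fields,
       cell_size = cell, lapse = lapse)
}

#' Write simulated climate grids as ESRI ASCII files
#'
#' One `.asc` per variable per day (`<variable>_<date>.asc`), plus
#' `elevation.asc` and `stations.csv`.
#'
#' @param climate the `climate` element of a [simulate_herd()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_climate <- function(climate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (var in names(climate$grids)) {
    for (key in names(climate$grids[[var]])) {
      write_asc_grid(climate$grids[[var]][[key]],
                     file.path(dir, sprintf("%s_%s.asc", var, key)))
    }
  }
  g1 <- climate$grids[[1]][[1]]
  if (!is.null(g1$reference_elevation)) {
    write_asc_grid(climate_grid("elevation", g1$date, g1$xll, g1$yll,
                                g1$cell_size, g1$reference_elevation),
                   file.path(dir, "elevation.asc"))
  }
  utils::write.csv(climate$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
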