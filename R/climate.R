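## Climate exposure covariates at alp locations.
##
## The temperature-humidity index (THI) summarises heat load from maximum
## temperature and relative humidity; the cold stress index (CSI) summarises
## cold load from mean temperature, wind speed and rainfall. Gridded
## temperature is sampled at the nearest cell and lapse-corrected to the alp
## altitude; station variables (RH, wind) are interpolated by squared
## inverse-distance weighting within 50 km. Exposures are daily indices
## averaged over the 3 or 30 calendar days strictly before the milk record.

#' Temperature-humidity index
#'
#' `THI = 0.8 T + (RH/100) (T - 14.4) + 46.4`, with `T` the maximum daily
#' temperature in deg C and `RH` the relative humidity in percent. At
#' `T = 14.4` the humidity term vanishes and the index is 57.92 regardless
#' of `RH`.
#'
#' @param t_max maximum daily temperature, deg C.
#' @param rh relative humidity, percent (0--100).
#' @return the dimensionless index (vectorised).
#' @export
thi <- function(t_max, rh) {
  if (any(!is.na(rh) & (rh < 0 | rh > 100))) {
    stop("relative humidity must lie in [0, 100] percent", call. = FALSE)
  }
  0.8 * t_max + (rh / 100) * (t_max - 14.4) + 46.4
}

#' Cold stress index
#'
#' `CSI = (11.7 + 3.1 sqrt(WS)) (40 - T) + 481 + 418 (1 - exp(-0.04 rain))`,
#' with `WS` the daily mean wind speed (m/s), `T` the mean daily temperature
#' (deg C) and `rain` the daily precipitation (mm). The rain term is bounded
#' by 418; at `T = 40` with no rain the index is 481 for any wind speed.
#'
#' @param ws daily mean wind speed, m/s (>= 0).
#' @param t_mean mean daily temperature, deg C.
#' @param rain daily precipitation, mm (>= 0).
#' @return the dimensionless index (vectorised).
#' @export
csi <- function(ws, t_mean, rain) {
  if (any(!is.na(ws) & ws < 0)) stop("wind speed must be >= 0", call. = FALSE)
  if (any(!is.na(rain) & rain < 0)) stop("rainfall must be >= 0", call. = FALSE)
  (11.7 + 3.1 * sqrt(ws)) * (40 - t_mean) + 481 + 418 * (1 - exp(-0.04 * rain))
}

#' Inverse-distance-weighted interpolation
#'
#' Weighted mean of station values with weights `distance^-power`, using only
#' stations within `max_dist` of the query point. A station at (numerically)
#' zero distance returns its value exactly.
#'
#' @param easting,northing station coordinates, m.
#' @param value station values.
#' @param x,y query coordinates, m.
#' @param power exponent of the distance weight (default 2, squared IDW).
#' @param max_dist maximum station distance in m (default 50 km).
#' @return the interpolated value, or `NA` if no station lies within
#'   `max_dist` (a missing exposure, excluded downstream).
#' @export
idw <- function(easting, northing, value, x, y, power = 2, max_dist = 50000) {
  d <- sqrt((easting - x)^2 + (northing - y)^2)
  ok <- !is.na(value) & d <= max_dist
  if (!any(ok)) return(NA_real_)
  d <- d[ok]; v <- value[ok]
  hit <- d < 1e-9
  if (any(hit)) return(mean(v[hit]))
  w <- d^(-power)
  sum(w * v) / sum(w)
}

#' Elevation lapse correction of temperature
#'
#' Maps a temperature valid at `grid_elev` to `site_elev` with a constant
#' gradient (default -0.45 deg C per 100 m, the conventional observed value
#' for this terrain). The correction is its own inverse under an elevation
#' swap.
#'
#' @param t temperature, deg C.
#' @param grid_elev elevation the value refers to, m.
#' @param site_elev target elevation, m.
#' @param gradient deg C per 100 m (default -0.45).
#' @return corrected temperature (vectorised).
#' @export
lapse_correct <- function(t, grid_elev, site_elev, gradient = -0.45) {
  if (any(!is.finite(grid_elev) | !is.finite(site_elev))) {
    stop("elevations must be finite", call. = FALSE)
  }
  t + gradient * (site_elev - grid_elev) / 100
}

# daily THI and CSI at one alp on a set of dates.
# grids: list with elements t_max, t_mean, rain, each a list of climate_grid
# keyed by "YYYY-MM-DD"; stations: data.frame(station_id, easting, northing,
# elevation_m, variable, date, value) with variable in {"rh","ws"}.
.daily_indices <- function(alp, dates, grids, stations, gradient, power, max_dist) {
  out <- data.frame(date = dates, thi = NA_real_, csi = NA_real_)
  st <- stations[stations$date %in% as.character(dates), , drop = FALSE]
  for (j in seq_along(dates)) {
    key <- as.character(dates[j])
    g_tmax <- grids$t_max[[key]]; g_tmean <- grids$t_mean[[key]]
    g_rain <- grids$rain[[key]]
    if (is.null(g_tmax) || is.null(g_tmean) || is.null(g_rain)) next
    s_tmax <- grid_sample(g_tmax, alp$easting, alp$northing)
    s_tmean <- grid_sample(g_tmean, alp$easting, alp$northing)
    s_rain <- grid_sample(g_rain, alp$easting, alp$northing)
    if (is.na(s_tmax$value) || is.na(s_tmean$value) || is.na(s_rain$value)) next
    tmax <- lapse_correct(s_tmax$value, s_tmax$elevation, alp$altitude_m, gradient)
    tmean <- lapse_correct(s_tmean$value, s_tmean$elevation, alp$altitude_m, gradient)
    sd_ <- st[st$date == key, , drop = FALSE]
    rh_st <- sd_[sd_$variable == "rh", , drop = FALSE]
    ws_st <- sd_[sd_$variable == "ws", , drop = FALSE]
    rh <- if (nrow(rh_st)) idw(rh_st$easting, rh_st$northing, rh_st$value,
                               alp$easting, alp$northing, power, max_dist) else NA_real_
    ws <- if (nrow(ws_st)) idw(ws_st$easting, ws_st$northing, ws_st$value,
                               alp$easting, alp$northing, power, max_dist) else NA_real_
    if (!is.na(rh)) {
      rh <- min(max(rh, 0), 100)   # interpolation cannot leave station range, but guard
      out$thi[j] <- thi(tmax, rh)
    }
    if (!is.na(ws)) out$csi[j] <- csi(max(ws, 0), tmean, s_rain$value)
  }
  out
}

#' Compute windowed THI/CSI exposures for alp test-day records
#'
#' For each alp record, daily THI and CSI are evaluated at the alp position
#' (grid temperatures lapse-corrected to the alp altitude, station RH/wind
#' interpolated by squared IDW) and averaged over the `window_days` calendar
#' days strictly preceding the record date (the record day itself is
#' excluded). Any missing day in the window makes the exposure `NA`; such
#' records are excluded from climate-factor contrasts but still enter curve
#' fitting.
#'
#' @param records,lactations,alps herd tables (QC-filtered).
#' @param climate a list with `grids` (per-variable lists of `climate_grid`
#'   keyed by ISO date) and `stations` (a station series table), as produced
#'   by [simulate_herd()] or assembled from [read_asc_grid()] output.
#' @param window_days 3 or 30.
#' @param gradient lapse gradient, deg C per 100 m.
#' @param power,max_dist IDW settings (see [idw()]).
#' @return a data.frame with `lactation_id`, `record_date`, `thi`, `csi`,
#'   row-aligned with the alp records of `records` (lowland records are
#'   omitted).
#' @export
compute_exposure <- function(records, lactations, alps, climate,
                             window_days = 3, gradient = -0.45,
                             power = 2, max_dist = 50000) {
  if (!window_days %in% c(3L, 30L)) {
    stop("window_days must be 3 or 30", call. = FALSE)
  }
  rec <- as.data.frame(records)
  rec <- rec[rec$site == "alp", , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(lactation_id = character(0), record_date = as.Date(character(0)),
                      thi = numeric(0), csi = numeric(0)))
  }
  stations <- as.data.frame(climate$stations)
  stations$date <- as.character(stations$date)
  out <- data.frame(lactation_id = rec$lactation_id, record_date = rec$record_date,
                    thi = NA_real_, csi = NA_real_)
  ## cache daily indices per (alp, date)
  cache <- new.env(parent = emptyenv())
  alps <- as.data.frame(alps)
  for (i in seq_len(nrow(rec))) {
    aid <- rec$alp_id[i]
    alp <- alps[match(aid, alps$alp_id), , drop = FALSE]
    if (is.na(aid) || !nrow(alp) || is.na(alp$easting)) next
    days <- rec$record_date[i] - seq_len(window_days)
    keys <- paste0(aid, "|", as.character(days))
    need <- !vapply(keys, exists, logical(1), envir = cache)
    if (any(need)) {
      di <- .daily_indices(alp, days[need], grids = climate$grids,
                           stations = stations, gradient = gradient,
                           power = power, max_dist = max_dist)
      for (j in seq_len(nrow(di))) {
        assign(keys[need][j], c(di$thi[j], di$csi[j]), envir = cache)
      }
    }
    vals <- vapply(keys, get, numeric(2), envir = cache)
    if (!anyNA(vals[1, ])) out$thi[i] <- mean(vals[1, ])
    if (!anyNA(vals[2, ])) out$csi[i] <- mean(vals[2, ])
  }
  out
}
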