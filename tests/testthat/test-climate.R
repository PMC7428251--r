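# Climate indices, interpolation, lapse correction, grids, exposures.

test_that("THI closed forms and monotonicity", {
  for (rh in c(0, 37, 100)) expect_equal(thi(14.4, rh), 57.92)
  expect_equal(thi(25, 50), 0.8 * 25 + 0.5 * (25 - 14.4) + 46.4)  # 71.7
  expect_equal(thi(25, 50), 71.7)
  expect_equal(thi(0, 100), 32.0)
  expect_error(thi(20, 140), "humidity")
  # strictly increasing in T at fixed RH; increasing in RH iff T > 14.4
  tt <- seq(-10, 35, by = 0.5)
  expect_true(all(diff(thi(tt, 60)) > 0))
  expect_true(thi(20, 80) > thi(20, 20))
  expect_true(thi(10, 80) < thi(10, 20))
})

test_that("CSI closed forms, bounds and monotonicity", {
  for (ws in c(0, 3, 12)) expect_equal(csi(ws, 40, 0), 481)
  expect_equal(csi(0, 0, 0), 11.7 * 40 + 481)  # 949
  expect_equal(csi(0, 0, 0), 949)
  expect_equal(csi(5, 40, 1e9), 481 + 418)     # rain term saturates at 418
  expect_error(csi(-1, 10, 0), "wind")
  expect_error(csi(1, 10, -2), "rain")
  tt <- seq(-20, 39, by = 1)
  expect_true(all(diff(csi(2, tt, 1)) < 0))
  expect_true(csi(9, 5, 1) > csi(1, 5, 1))
  expect_true(csi(2, 5, 20) > csi(2, 5, 0))
  expect_true(all(418 * (1 - exp(-0.04 * c(0.1, 5, 50, 500))) < 418))
})

test_that("IDW interpolation: exactness, symmetry, range, cutoff", {
  expect_equal(idw(c(0, 10000), c(0, 0), c(7.3, 99), 0, 0), 7.3)
  expect_equal(idw(c(-5000, 5000), c(0, 0), c(10, 20), 0, 0), 15)
  # distances 1 and 2, values 0 and 15, squared weights -> 3
  expect_equal(idw(c(1, 2), c(0, 0), c(0, 15), 0, 0), 3.0)
  expect_true(is.na(idw(c(60000), c(0), c(5), 0, 0, max_dist = 50000)))
  set.seed(42)
  for (i in 1:20) {
    v <- runif(6, -5, 25)
    out <- idw(runif(6, 0, 2e4), runif(6, 0, 2e4), v, 1e4, 1e4, max_dist = 1e9)
    expect_gte(out, min(v)); expect_lte(out, max(v))
  }
})

test_that("lapse correction is linear in elevation and self-inverse", {
  expect_equal(lapse_correct(10, 1200, 1200), 10)
  expect_equal(lapse_correct(10, 1000, 1500), 7.75)
  expect_equal(lapse_correct(10, 1500, 1000), 12.25)
  t2 <- lapse_correct(lapse_correct(8, 900, 2100), 2100, 900)
  expect_equal(t2, 8)
  expect_error(lapse_correct(10, Inf, 1000), "finite")
})

test_that("ESRI ASCII grid round trip and nearest-cell sampling", {
  m <- matrix(seq_len(12), nrow = 3, ncol = 4)   # row 1 = north
  g <- climate_grid("t_max", "2007-06-01", xll = 1000, yll = 2000,
                    cell_size = 100, values = m)
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc_grid(g, path)
  back <- read_asc_grid(path, variable = "t_max", date = "2007-06-01")
  expect_equal(back$values, m)
  expect_equal(back$cell_size, 100)
  expect_equal(back$xll, 1000)
  # sampling: cell centres; northing near the top maps to row 1
  s <- grid_sample(g, easting = 1050, northing = 2250)
  expect_equal(s$value, m[1, 1])
  s <- grid_sample(g, easting = 1350, northing = 2050)
  expect_equal(s$value, m[3, 4])
  expect_true(is.na(grid_sample(g, 900, 2050)$value))
})

test_that("reference elevation must match the value grid shape", {
  expect_error(climate_grid("t_max", "2007-06-01", 0, 0, 100,
                            matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("windowed exposure equals the mean of hand-built daily indices", {
  # one alp, constant-in-space grids, three days with distinct temperatures
  alp <- data.frame(alp_id = "A1", easting = 500, northing = 500,
                    altitude_m = 1500, region = "x", stringsAsFactors = FALSE)
  days <- as.Date("2007-07-10") + 0:2
  tmaxes <- c(18, 20, 22)
  grids <- list(t_max = list(), t_mean = list(), rain = list())
  for (i in 1:3) {
    key <- as.character(days[i])
    grids$t_max[[key]] <- climate_grid("t_max", days[i], 0, 0, 1000,
                                       matrix(tmaxes[i], 1, 1), matrix(1500, 1, 1))
    grids$t_mean[[key]] <- climate_grid("t_mean", days[i], 0, 0, 1000,
                                        matrix(tmaxes[i] - 6, 1, 1), matrix(1500, 1, 1))
    grids$rain[[key]] <- climate_grid("rain", days[i], 0, 0, 1000, matrix(2, 1, 1))
  }
  stations <- expand.grid(station_id = c("S1", "S2"), date = as.character(days),
                          stringsAsFactors = FALSE)
  stations <- rbind(
    transform(stations, easting = ifelse(station_id == "S1", 0, 1000),
              northing = 500, elevation_m = 1500, variable = "rh", value = 70),
    transform(stations, easting = ifelse(station_id == "S1", 0, 1000),
              northing = 500, elevation_m = 1500, variable = "ws", value = 3))
  cal <- as.Date("2006-10-01")
  rec_date <- days[3] + 1          # window = the three constructed days
  h <- toy_herd(dims = as.integer(rec_date - cal), calving = cal,
                site = "alp", alp_id = "A1")
  ex <- compute_exposure(h$records, h$lactations, alp,
                         list(grids = grids, stations = stations), window_days = 3)
  expect_equal(ex$thi, mean(thi(tmaxes, 70)))
  expect_equal(ex$csi, mean(csi(3, tmaxes - 6, 2)))

  # grid elevation != alp altitude: lapse correction applied per day
  for (key in names(grids$t_max)) {
    grids$t_max[[key]]$reference_elevation <- matrix(1000, 1, 1)
  }
  ex2 <- compute_exposure(h$records, h$lactations, alp,
                          list(grids = grids, stations = stations), window_days = 3)
  expect_equal(ex2$thi, mean(thi(tmaxes - 0.45 * 5, 70)))

  # a missing day in the window -> missing exposure
  grids$t_max[[as.character(days[2])]] <- NULL
  ex3 <- compute_exposure(h$records, h$lactations, alp,
                          list(grids = grids, stations = stations), window_days = 3)
  expect_true(is.na(ex3$thi))
})

test_that("exposure matches a brute-force per-day recomputation on synthetic fields", {
  cfg <- sim_config(n_cows = 40, seed = 14, years = 2006, n_alps = 5,
                    climate = list(n_stations = 25, station_noise = 0.2))
  sim <- simulate_herd(cfg)
  ex <- compute_exposure(sim$records, sim$lactations, sim$alps, sim$climate,
                         window_days = 3)
  expect_gt(nrow(ex), 10)
  alp_rec <- sim$records[sim$records$site == "alp", ]
  st <- sim$climate$stations
  i <- which(!is.na(ex$thi))[c(1, 5, 9)]
  for (j in i) {
    alp <- sim$alps[sim$alps$alp_id == alp_rec$alp_id[j], ]
    daily_thi <- daily_csi <- numeric(3)
    for (d in 1:3) {
      day <- alp_rec$record_date[j] - d
      key <- as.character(day)
      tm <- grid_sample(sim$climate$grids$t_max[[key]], alp$easting, alp$northing)
      tmn <- grid_sample(sim$climate$grids$t_mean[[key]], alp$easting, alp$northing)
      rn <- grid_sample(sim$climate$grids$rain[[key]], alp$easting, alp$northing)
      ss <- st[st$date == key, ]
      rh <- with(ss[ss$variable == "rh", ],
                 idw(easting, northing, value, alp$easting, alp$northing))
      ws <- with(ss[ss$variable == "ws", ],
                 idw(easting, northing, value, alp$easting, alp$northing))
      daily_thi[d] <- thi(lapse_correct(tm$value, tm$elevation, alp$altitude_m),
                          min(max(rh, 0), 100))
      daily_csi[d] <- csi(max(ws, 0),
                          lapse_correct(tmn$value, tmn$elevation, alp$altitude_m),
                          rn$value)
    }
    expect_equal(ex$thi[j], mean(daily_thi), tolerance = 1e-10)
    expect_equal(ex$csi[j], mean(daily_csi), tolerance = 1e-10)
  }
})
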