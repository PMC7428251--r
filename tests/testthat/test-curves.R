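# Averaged cohort curves, eligibility window, transitions, reweighting.

test_that("per-DIM means, counts and the eligibility window", {
  cal <- as.Date("2006-09-15")
  h1 <- toy_herd(dims = 50, calving = cal, milk = 20, id = "1")
  h2 <- toy_herd(dims = 50, calving = cal, milk = 22, id = "2")
  # a lowland record dated inside the alping window must be excluded
  h3 <- toy_herd(dims = as.integer(as.Date("2007-06-01") - cal), calving = cal,
                 milk = 30, id = "3")
  h <- bind_herds(h1, h2, h3)
  cv <- build_curve(h$records, h$lactations, "Sep",
                    transitions = c(t1 = NA_real_, t2 = NA_real_))
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$dim, 50)
  expect_equal(cv$mean_yield, 21.0)
  expect_equal(cv$n_obs, 2L)
})

test_that("per-DIM means equal an independent group-by oracle", {
  sim <- simulate_herd(sim_config(n_cows = 300, seed = 21))
  cv <- build_curve(sim$records, sim$lactations, 9)
  # oracle: plain split/tapply over eligible September records
  lact <- sim$lactations[format(sim$lactations$calving_date, "%m") == "09", ]
  rec <- sim$records[sim$records$lactation_id %in% lact$lactation_id, ]
  md <- format(rec$record_date, "%m-%d")
  in_win <- md >= "05-15" & md <= "08-31"
  rec <- rec[(in_win & rec$site == "alp") | (!in_win & rec$site == "lowland"), ]
  dim_ <- as.integer(rec$record_date -
                       lact$calving_date[match(rec$lactation_id, lact$lactation_id)])
  means <- tapply(rec$milk_kg, dim_, mean)
  counts <- tapply(rec$milk_kg, dim_, length)
  expect_equal(cv$dim, as.integer(names(means)))
  expect_equal(cv$mean_yield, as.numeric(means))
  expect_equal(cv$n_obs, unname(as.integer(counts)))
  expect_equal(sum(cv$n_obs), nrow(rec))
  # permutation invariance of the averaging
  shuf <- sim$records[sample.int(nrow(sim$records)), ]
  cv2 <- build_curve(shuf, sim$lactations, 9)
  expect_equal(as.data.frame(cv2), as.data.frame(cv))
})

test_that("transition location: medians and calendar mode", {
  cal <- as.Date("2006-09-15")
  mk <- function(first_alp, id) {
    dims <- c(20, seq(first_alp, first_alp + 90, 30), first_alp + 120)
    site <- c("lowland", rep("alp", 4), "lowland")
    toy_herd(dims, cal, site = site, alp_id = "A1", id = id)
  }
  h <- bind_herds(mk(240, "a"), mk(245, "b"), mk(250, "c"))
  tr <- locate_transitions(h$records, h$lactations, 9, mode = "observed")
  expect_equal(unname(tr["t1"]), 245)   # odd-n median of {240, 245, 250}
  expect_equal(unname(tr["t2"]), 245 + 90)

  h1 <- mk(245, "z")
  tr1 <- locate_transitions(h1$records, h1$lactations, 9, mode = "observed")
  expect_equal(unname(tr1["t1"]), 245)  # degenerate single-lactation median

  # calendar mode: calving 1 Sep, ascent 15 May -> 256 days
  h2 <- toy_herd(dims = c(20, 260), calving = as.Date("2006-09-01"),
                 site = c("lowland", "alp"), alp_id = "A1")
  tr2 <- locate_transitions(h2$records, h2$lactations, 9, mode = "calendar")
  expect_equal(unname(tr2["t1"]),
               as.numeric(as.Date("2007-05-15") - as.Date("2006-09-01")))
  expect_equal(unname(tr2["t1"]), 256)

  # no alp records -> error
  h3 <- toy_herd(dims = c(20, 50))
  expect_error(locate_transitions(h3$records, h3$lactations, 9), "no alp records")
})

test_that("midpoint transitions recover a known calendar on simulated sampling", {
  sim <- simulate_herd(sim_config(n_cows = 2000, seed = 8, years = 2005,
                                  calving_month_weights = c(`9` = 1)))
  tr <- locate_transitions(sim$records, sim$lactations, 9, mode = "midpoint")
  expect_lt(abs(tr["t1"] - 242), 2)
  expect_lt(abs(tr["t2"] - 350), 2)
})

test_that("pre-alping reweighting multiplies only pre-t1 weights", {
  cal <- as.Date("2006-09-15")
  dims <- c(240, 241, 242)                # 13-15 May; window opens on the 15th
  h <- toy_herd(dims, cal, site = c("lowland", "lowland", "alp"), alp_id = "A1")
  h$records$milk_kg <- c(15, 14, 13)
  cv <- build_curve(h$records, h$lactations, 9,
                    transitions = c(t1 = 241, t2 = 350))
  cv$n_obs <- c(7L, 7L, 7L); cv$weight <- c(7, 7, 7)
  rw <- reweight_pre_alping(cv, 100)
  expect_equal(rw$weight, c(700, 7, 7))   # boundary dim = t1 is alping
  expect_equal(reweight_pre_alping(cv, 1)$weight, cv$weight)
})

test_that("curve CSV round trip preserves points and transitions", {
  sim <- simulate_herd(sim_config(n_cows = 150, seed = 5))
  cv <- build_curve(sim$records, sim$lactations, 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, path)
  back <- read_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(cv))
  expect_equal(attr(back, "t1"), attr(cv, "t1"))
  expect_equal(attr(back, "t2"), attr(cv, "t2"))
})

test_that("curve building commutes with splitting and weighted pooling", {
  sim <- simulate_herd(sim_config(n_cows = 400, seed = 31))
  cv <- build_curve(sim$records, sim$lactations, 10)
  lact <- sim$lactations[format(sim$lactations$calving_date, "%m") == "10", ]
  half <- lact$lactation_id[seq_len(nrow(lact)) %% 2 == 0]
  r1 <- sim$records[sim$records$lactation_id %in% half, ]
  r2 <- sim$records[!sim$records$lactation_id %in% half, ]
  cva <- build_curve(r1, sim$lactations, 10, transitions = c(t1 = NA_real_, t2 = NA_real_))
  cvb <- tryCatch(build_curve(r2, sim$lactations, 10,
                              transitions = c(t1 = NA_real_, t2 = NA_real_)),
                  error = function(e) NULL)
  pooled <- rbind(data.frame(dim = cva$dim, y = cva$mean_yield, n = cva$n_obs),
                  if (!is.null(cvb)) data.frame(dim = cvb$dim, y = cvb$mean_yield,
                                                n = cvb$n_obs))
  agg_y <- tapply(pooled$y * pooled$n, pooled$dim, sum) /
    tapply(pooled$n, pooled$dim, sum)
  expect_equal(as.numeric(agg_y[as.character(cv$dim)]), cv$mean_yield)
})
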