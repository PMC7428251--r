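# The extended Wilmink model: design, WLS fits, integrals, loss, k search.

mk_curve <- function(dims, y, w = rep(1, length(dims)), t1 = 242, t2 = 350) {
  structure(data.frame(dim = dims, mean_yield = y, n_obs = as.integer(round(w)),
                       weight = w),
            class = c("averaged_curve", "data.frame"),
            calving_month = 9L, t1 = t1, t2 = t2)
}
p0 <- c(a = 22, b = -8, c = -0.02, d = -0.08, f = 1.5, g = -0.04, k = 0.1)

test_that("design rows gate the alping terms correctly", {
  X <- design_matrix(c(100, 242, 243, 350, 351, 400), k = 0.1, t1 = 242, t2 = 350)
  expect_equal(colnames(X), c("a", "b", "c", "d", "f", "g"))
  expect_equal(X[1, c("d", "f", "g")], c(d = 0, f = 0, g = 0))  # pre-alping: pure Wilmink
  expect_equal(unname(X[2, "d"]), 0)               # hinge starts after t1
  expect_equal(unname(X[3, "d"]), 1)
  expect_equal(X[4, c("f", "g")], c(f = 0, g = 0))  # return day itself: not boosted
  expect_equal(X[5, c("f", "g")], c(f = 1, g = 1))  # ceiling(1/305) = 1
  expect_equal(unname(X[6, "f"]), 1)               # clamp keeps the indicator binary
  Xw <- design_matrix(100, variant = "wilmink")
  expect_equal(unname(Xw), unname(X[1, 1:3, drop = FALSE]))
  expect_error(design_matrix(1, t1 = 300, t2 = 250), "t1.*t2")
})

test_that("noise-free curves are recovered exactly", {
  dims <- c(seq(6, 500, by = 7))
  y <- truth_yield(dims, as.list(p0), 242, 350)
  ft <- fit_lactation(mk_curve(dims, y), "alping_full")
  expect_equal(unname(ft$params), unname(p0[1:6]), tolerance = 1e-8)
  # truncated variant: only up to t2, no f/g
  ft2 <- fit_lactation(mk_curve(dims, y), "alping_truncated")
  expect_equal(names(ft2$params), c("a", "b", "c", "d"))
  expect_equal(ft2$model_end, 350)
  expect_equal(unname(ft2$params), unname(p0[1:4]), tolerance = 1e-8)
})

test_that("fits equal the normal-equations oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    # draw points from each regime so every column is identifiable
    dims <- sort(c(sample(5:240, sample(5:12, 1)),
                   sample(243:348, sample(3:8, 1)),
                   sample(352:500, sample(3:8, 1))))
    n <- length(dims)
    y <- truth_yield(dims, as.list(p0), 242, 350) + rnorm(n, 0, 2)
    w <- runif(n, 0.5, 40)
    cv <- mk_curve(dims, y, w)
    ft <- fit_lactation(cv, "alping_full")
    X <- design_matrix(dims, 0.1, 242, 350, "alping_full")
    expect_equal(unname(ft$params), unname(drop(ne_solve(X, y, w))),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  dims <- rep(c(10, 20, 30, 40, 50, 60, 70), 2)   # all pre-alping
  y <- truth_yield(dims, as.list(p0), 242, 350)
  expect_error(fit_lactation(mk_curve(dims, y), "alping_full"), "singular|collinear")
})

test_that("milk loss formula and its quadratic scaling", {
  expect_equal(milk_loss(-0.08, 60), 144)
  expect_equal(milk_loss(0, 60), 0)
  expect_equal(milk_loss(-0.02, 100), 100)
  expect_equal(milk_loss(-0.05, 2 * 37), 4 * milk_loss(-0.05, 37))
  expect_gt(milk_loss(0.08, 60), 0)       # magnitude, sign-independent
  expect_error(milk_loss(-0.08, -1), ">= 0")
})

test_that("closed-form production integral matches quadrature and algebra", {
  dims <- seq(6, 500, by = 4)
  y <- truth_yield(dims, as.list(p0), 242, 350)
  ft <- fit_lactation(mk_curve(dims, y), "alping_full")
  # pure polynomial case
  p_lin <- c(a = 20, b = 0, c = -0.03, d = 0, f = 0, g = 0, k = 0.1)
  ylin <- truth_yield(dims, as.list(p_lin), 242, 350)
  flin <- fit_lactation(mk_curve(dims, ylin), "alping_full")
  expect_equal(integrate_production(flin, 10, 200),
               20 * 190 + (-0.03) * (200^2 - 10^2) / 2, tolerance = 1e-6)
  # quadrature oracle at 0.1-day steps, within 0.01 %
  for (iv in list(c(5, 200), c(200, 400), c(5, 500), c(340, 360))) {
    q <- quadrature_production(ft, iv[1], iv[2])
    expect_equal(integrate_production(ft, iv[1], iv[2]), q,
                 tolerance = 1e-4)
  }
  # alping deficit equals the loss formula while t_end <= t2
  pd <- as.list(c(p0)); pd$f <- 0; pd$g <- 0
  p0d <- pd; p0d$d <- 0
  fd <- fit_lactation(mk_curve(dims, truth_yield(dims, pd, 242, 350)), "alping_full")
  f0 <- fit_lactation(mk_curve(dims, truth_yield(dims, p0d, 242, 350)), "alping_full")
  deficit <- integrate_production(f0, 242, 340) - integrate_production(fd, 242, 340)
  expect_equal(deficit, milk_loss(pd$d, 340 - 242), tolerance = 1e-6)
  # domain errors
  expect_error(integrate_production(ft, 10, 600), "horizon")
  expect_error(integrate_production(ft, 50, 50), "t_start")
})

test_that("predicted curve is continuous except a jump of f at t2", {
  dims <- seq(6, 500, by = 4)
  ft <- fit_lactation(mk_curve(dims, truth_yield(dims, as.list(p0), 242, 350)),
                      "alping_full")
  lo <- seq(20, 350, by = 0.25)                  # past the steep early rise
  hi <- seq(350.25, 500, by = 0.25)              # strictly after t2
  expect_lt(max(abs(diff(predict(ft, lo)))), 0.05)  # smooth left of the jump
  expect_lt(max(abs(diff(predict(ft, hi)))), 0.05)  # smooth right of the jump
  jump <- predict(ft, 350 + 1e-9) - predict(ft, 350)
  expect_equal(unname(jump), unname(ft$params["f"]), tolerance = 1e-6)
})

test_that("model nesting: alping terms inert before t1, loglik ordering", {
  sim <- simulate_herd(sim_config(n_cows = 600, seed = 13, years = 2005,
                                  calving_month_weights = c(`9` = 1)))
  cv <- build_curve(sim$records, sim$lactations, 9)
  pre <- cv[cv$dim < attr(cv, "t1"), ]
  attr(pre, "t1") <- attr(cv, "t1"); attr(pre, "t2") <- attr(cv, "t2")
  fw <- fit_lactation(pre, "wilmink")
  # with only pre-alping points the alping columns are identically zero, so
  # the full design is singular there; the Wilmink fit is the comparable model
  expect_equal(names(fw$params), c("a", "b", "c"))
  full <- fit_lactation(cv, "alping_full")
  w_only <- fit_lactation(cv, "wilmink", model_end = 500)
  expect_gte(full$loglik, w_only$loglik)         # nested models
})

test_that("k profiling recovers a known decay and flags unidentifiable b", {
  dims <- seq(5, 300, by = 5)
  pk <- as.list(c(p0)); pk$k <- 0.2
  y <- truth_yield(dims, pk, 242, 350)
  cv <- mk_curve(dims, y, t1 = 242, t2 = 350)
  expect_equal(estimate_k(cv), 0.2, tolerance = 1e-3)
  yb0 <- truth_yield(dims, modifyList(pk, list(b = 0)), 242, 350)
  expect_warning(k0 <- estimate_k(mk_curve(dims, yb0, t1 = 242, t2 = 350)),
                 "flat|unidentifiable")
  expect_equal(k0, 0.1)
  # noisy recovery within a broad band
  set.seed(4)
  yn <- y + rnorm(length(dims), 0, 0.3)
  expect_lt(abs(estimate_k(mk_curve(dims, yn, t1 = 242, t2 = 350)) - 0.2), 0.05)
})

test_that("knot refinement finds the true transition days", {
  # daily points, as averaged cohort curves have: the return day is then
  # identified exactly (coarser grids cannot separate neighbouring days)
  dims <- seq(6, 480, by = 1)
  y <- truth_yield(dims, as.list(p0), 245, 352)
  cv <- mk_curve(dims, y, t1 = 240, t2 = 348)   # deliberately wrong starts
  tt <- refine_transitions(cv)
  expect_equal(unname(tt["t2"]), 352)
  expect_lt(abs(tt["t1"] - 245), 0.75)
  ft <- fit_lactation(cv, "alping_full", refine = TRUE)
  expect_equal(unname(ft$params), unname(p0[1:6]), tolerance = 1e-6)
})
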