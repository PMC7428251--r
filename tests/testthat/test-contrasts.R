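# Tertile grouping, G-tests, Bonferroni, two-group contrasts.

test_that("tertile grouping on exact and skewed samples", {
  g <- assign_groups(1:9, "t1_vs_t3")
  expect_equal(which(g$labels == "t1"), 1:3)
  expect_equal(which(g$labels == "t3"), 7:9)

  g2 <- assign_groups(1:9, "t2_vs_t3")
  expect_equal(which(g2$labels == "t2"), 4:6)
  expect_equal(which(g2$labels == "t3"), 7:9)

  expect_error(assign_groups(rep(5, 20), "t1_vs_t3"),
               class = "alpcurve_contrast_infeasible")

  set.seed(7)
  v <- rexp(501)^2                      # heavily skewed
  g3 <- assign_groups(v, "t1_vs_t3")
  expect_equal(unname(g3$cutoffs), manual_quantile7(v, c(1/3, 2/3)))
  expect_true(all(v[which(g3$labels == "t1")] < g3$cutoffs[1]))
  expect_true(all(v[which(g3$labels == "t3")] > g3$cutoffs[2]))
})

test_that("explicit grouping requires exactly two levels", {
  g <- assign_groups(c("N", "E", "N", NA, "E"), "explicit")
  expect_equal(g$levels, c("E", "N"))
  expect_error(assign_groups(c("a", "b", "c"), "explicit"),
               class = "alpcurve_contrast_infeasible")
})

test_that("Bonferroni adjustment: examples, cap and dominance", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1.0)
  set.seed(11)
  p <- runif(50)
  expect_true(all(bonferroni(p, 7) >= p))
  expect_equal(order(bonferroni(p, 3)), order(pmin(1, p * 3)))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("identical groups give a null contrast: G ~ 0, p ~ 1, delta_d = 0", {
  sim <- simulate_herd(sim_config(n_cows = 400, seed = 5, years = 2005,
                                  calving_month_weights = c(`9` = 1)))
  dup <- function(df, suf) {
    df$lactation_id <- paste0(df$lactation_id, suf)
    df
  }
  lact2 <- rbind(dup(sim$lactations, "_A"), dup(sim$lactations, "_B"))
  lact2$cow_id <- paste0(lact2$cow_id, rep(c("_A", "_B"), each = nrow(sim$lactations)))
  rec2 <- rbind(dup(sim$records, "_A"), dup(sim$records, "_B"))
  ds <- list(records = rec2, lactations = lact2, cows = sim$cows, alps = sim$alps)
  lab <- setNames(rep(c("gA", "gB"), each = nrow(sim$lactations)), lact2$lactation_id)
  fs <- factor_spec("ident", "environmental",
                    function(d) unname(lab[d$lactations$lactation_id]),
                    grouping = "explicit")
  res <- contrast_factor(fs, ds, 9)
  expect_lt(abs(res$g_stat), 1e-6)
  expect_gt(res$p_raw, 0.999)
  expect_lt(abs(res$delta_d), 1e-10)
  expect_lt(abs(res$pct_diff_alping), 1e-8)
})

test_that("a planted d contrast is recovered and significant", {
  tr1 <- list(a = 22, b = -8, c = -0.02, d = -0.08, f = 1.5, g = -0.04, k = 0.1)
  tr2 <- modifyList(tr1, list(d = -0.02))
  sim <- simulate_herd(sim_config(n_cows = 1500, seed = 23, years = 2005,
                                  calving_month_weights = c(`9` = 1),
                                  group_truth = list(tr1, tr2)))
  gg <- sim$truth$cow_params
  fs <- factor_spec("planted", "environmental",
                    function(d) gg$group[match(d$lactations$lactation_id,
                                               gg$lactation_id)],
                    grouping = "explicit")
  res <- contrast_factor(fs, sim, 9, m = 14)
  expect_lt(abs(abs(res$delta_d) - 0.06) / res$delta_d_se, 3)
  expect_lt(res$p_bonferroni, 0.05)
  # environmental variant: f and g are not estimated
  expect_false(any(c("f", "g") %in% names(res$joint_fit$params)))
  expect_equal(res$df, 1L)
  # the reference group is the less-impacted one (d = -0.02)
  ref_lab <- res$reference_group
  expect_equal(ref_lab, "g2")
  expect_gt(res$delta_d, 0)
})

test_that("relabelling groups flips signs but not the test", {
  tr1 <- list(a = 22, b = -8, c = -0.02, d = -0.06, f = 1.5, g = -0.04, k = 0.1)
  tr2 <- modifyList(tr1, list(d = -0.03, a = 21))
  sim <- simulate_herd(sim_config(n_cows = 800, seed = 29, years = 2005,
                                  calving_month_weights = c(`9` = 1),
                                  group_truth = list(tr1, tr2)))
  gg <- sim$truth$cow_params
  mk <- function(swap) {
    factor_spec("lab", "physiological", function(d) {
      g <- gg$group[match(d$lactations$lactation_id, gg$lactation_id)]
      if (swap) c(g1 = "zz", g2 = "aa")[g] else g
    }, grouping = "explicit")
  }
  r1 <- contrast_factor(mk(FALSE), sim, 9)
  r2 <- contrast_factor(mk(TRUE), sim, 9)
  expect_equal(r2$g_stat, r1$g_stat, tolerance = 1e-8)
  expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-8)
  expect_equal(abs(r2$delta_d), abs(r1$delta_d), tolerance = 1e-8)
  expect_equal(sort(unname(r2$production_alping)),
               sort(unname(r1$production_alping)), tolerance = 1e-6)
})

test_that("physiological contrasts vary all parameters over the full horizon", {
  sim <- simulate_herd(sim_config(n_cows = 900, seed = 31, years = 2005))
  fs <- default_factors()$lactation_number
  res <- contrast_factor(fs, sim, 9)
  expect_equal(res$df, 6L)
  expect_equal(res$fits[[1]]$model_end, 500)
  expect_true(all(is.finite(res$production_total)))
  expect_true(is.finite(res$pct_diff_total))
})

test_that("the G statistic agrees with an independent likelihood-ratio test", {
  skip_if_not_installed("lmtest")
  sim <- simulate_herd(sim_config(n_cows = 700, seed = 37, years = 2005,
                                  calving_month_weights = c(`9` = 1)))
  cv <- build_curve(sim$records, sim$lactations, 9)
  full <- fit_lactation(cv, "alping_full")
  wil <- fit_lactation(cv, "wilmink", model_end = 500)
  G <- 2 * (full$loglik - wil$loglik)
  lr <- lmtest::lrtest(wil$lm, full$lm)
  expect_equal(G, lr$Chisq[2], tolerance = 1e-8)
  expect_equal(pchisq(G, df = 3, lower.tail = FALSE), lr$`Pr(>Chisq)`[2],
               tolerance = 1e-8)
})
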