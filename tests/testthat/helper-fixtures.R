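# Shared fixtures: tiny hand-built herd tables and independent oracles.

# a minimal consistent herd with one cow/lactation and records at given DIMs
toy_herd <- function(dims = c(20, 50, 80), calving = as.Date("2006-09-15"),
                     site = "lowland", milk = 20, alp_id = NA_character_,
                     id = "1", parity = 1L, birth = calving - 1000,
                     insem = calving + 80) {
  n <- length(dims)
  list(
    records = data.frame(
      cow_id = paste0("C", id), lactation_id = paste0("L", id),
      record_date = calving + dims, milk_kg = rep_len(milk, n),
      fat_pct = 4, protein_pct = 3.4, scc = 80,
      site = rep_len(site, n),
      alp_id = ifelse(rep_len(site, n) == "alp", alp_id, NA_character_),
      stringsAsFactors = FALSE),
    lactations = data.frame(
      lactation_id = paste0("L", id), cow_id = paste0("C", id),
      parity = parity, calving_date = calving,
      insemination_dates = format(insem, "%Y-%m-%d"),
      alp_id = alp_id, next_calving_date = insem + 283,
      stringsAsFactors = FALSE),
    cows = data.frame(
      cow_id = paste0("C", id), breed = "Braunvieh", sire_breed = "Braunvieh",
      dam_breed = "Braunvieh", birth_date = birth, height_cm = 140,
      foot_angle = 5L, stringsAsFactors = FALSE),
    alps = data.frame(
      alp_id = "A1", easting = 2650000, northing = 1160000,
      altitude_m = 1800, region = "Northern Alps", stringsAsFactors = FALSE)
  )
}

# merge several toy herds (distinct ids) into one dataset
bind_herds <- function(...) {
  hs <- list(...)
  out <- list()
  for (tab in c("records", "lactations", "cows")) {
    out[[tab]] <- do.call(rbind, lapply(hs, `[[`, tab))
  }
  out$alps <- unique(do.call(rbind, lapply(hs, `[[`, "alps")))
  out
}

# type-7 quantile computed by explicit sort-and-interpolate, independent of
# stats::quantile
manual_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# brute-force normal-equations WLS: solve (X'WX) b = X'Wy
ne_solve <- function(X, y, w) {
  W <- diag(w, nrow = length(w))
  A <- t(X) %*% W %*% X
  b <- t(X) %*% W %*% y
  # column equilibration: the raw normal equations mix scales 1 and 500^2
  D <- diag(1 / sqrt(diag(A)), nrow = nrow(A))
  D %*% solve(D %*% A %*% D, D %*% b)
}

# numerical quadrature of a fitted curve at fine steps (trapezoid)
quadrature_production <- function(fit, t_start, t_end, step = 0.1) {
  # integrate each smooth piece separately so the jump at t2 is respected
  knots <- unlist(Filter(function(x) !is.null(x) && !is.na(x) &&
                           x > t_start && x < t_end,
                         list(fit$t1, fit$t2)))
  brk <- sort(unique(c(t_start, t_end, knots)))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    tt <- seq(brk[i], brk[i + 1], by = step)
    if (tail(tt, 1) < brk[i + 1]) tt <- c(tt, brk[i + 1])
    # stay strictly inside the piece so the indicator does not straddle
    yy <- predict(fit, pmin(pmax(tt, brk[i] + 1e-9), brk[i + 1] - 1e-9))
    total <- total + sum((tt[-1] - tt[-length(tt)]) *
                           (yy[-1] + yy[-length(yy)]) / 2)
  }
  total
}

# the extended model curve evaluated directly (independent of design_matrix)
truth_yield <- function(t, p, t1, t2) {
  p[["a"]] + p[["b"]] * exp(-p[["k"]] * t) + p[["c"]] * t +
    p[["d"]] * pmax(0, t - t1) +
    p[["f"]] * as.numeric(t > t2) +
    p[["g"]] * pmax(0, t - t2)
}
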