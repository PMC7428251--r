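## The Wilmink lactation curve and its transhumance extension.
##
## Wilmink:            Y(t) = a + b exp(-k t) + c t
## Alping extension:   Y(t) = a + b exp(-k t) + c t
##                            + d max(0, t - t1)                 (alping slope)
##                            + f 1{t > t2}                      (return boost)
##                            + g max(0, t - t2)                 (post-alp slope)
## with t the DIM, t1/t2 the cohort's alp-ascent/return DIM and k fixed at
## 0.1/day (which keeps the model linear in the parameters). The boost
## indicator is written min(1, max(0, ceiling((t - t2)/305))), i.e. a 0/1
## step at the return day, clamped so it stays binary past t2 + 305.
## Fits are weighted least squares on averaged cohort curves.

.variants <- c("wilmink", "alping_truncated", "alping_full")

#' Design matrix of the lactation model
#'
#' Columns are named after the model parameters: `a` (intercept), `b`
#' (exponential rise, `exp(-k t)`), `c` (linear slope, `t`); the alping
#' variants add `d` (`max(0, t - t1)`), and the full variant also `f` (the
#' 0/1 post-return boost) and `g` (`max(0, t - t2)`).
#'
#' @param t DIM values (>= 0).
#' @param k exponential decay constant, 1/day.
#' @param t1,t2 alp ascent / return DIM (required for the alping variants).
#' @param variant one of `"wilmink"`, `"alping_truncated"`, `"alping_full"`.
#' @return a numeric matrix with one row per element of `t`.
#' @export
design_matrix <- function(t, k = 0.1, t1 = NULL, t2 = NULL,
                          variant = c("alping_full", "alping_truncated", "wilmink")) {
  variant <- match.arg(variant)
  X <- cbind(a = rep(1, length(t)), b = exp(-k * t), c = t)
  if (variant == "wilmink") return(X)
  if (is.null(t1) || is.na(t1)) stop("t1 is required for alping variants", call. = FALSE)
  if (variant == "alping_full" || !is.null(t2)) {
    if (is.null(t2) || is.na(t2)) stop("t2 is required for alping_full", call. = FALSE)
    if (t1 >= t2) stop(sprintf("configuration error: t1 (%g) must be < t2 (%g)", t1, t2),
                       call. = FALSE)
  }
  X <- cbind(X, d = pmax(0, t - t1))
  if (variant == "alping_full") {
    X <- cbind(X,
               f = pmin(1, pmax(0, ceiling((t - t2) / 305))),
               g = pmax(0, t - t2))
  }
  X
}

#' Fit the lactation model to an averaged curve
#'
#' Weighted least squares minimising `sum w_i (y_i - yhat_i)^2`, via `lm()`.
#' For `"alping_truncated"` the fitting horizon is `t2`: the model runs only
#' to the end of the alping season and the `f`/`g` terms are not estimated
#' (the form used for environmental contrasts). `"alping_full"` fits the
#' whole curve up to 500 DIM. The reported log-likelihood is the weighted
#' Gaussian log-likelihood at the MLE variance (weights as relative
#' precisions), so nested fits are directly comparable in a G-test.
#'
#' @param curve an `averaged_curve` (its `weight` column is used).
#' @param variant model variant, see [design_matrix()].
#' @param k decay constant, fixed (default 0.1/day).
#' @param t1,t2 optional overrides of the curve's transition attributes.
#' @param model_end optional fitting horizon in DIM (defaults: `t2` for the
#'   truncated variant, 500 otherwise).
#' @param refine if `TRUE` (full variant only), the transition knots are
#'   refined with [refine_transitions()] before fitting.
#' @return a `lactation_fit` with elements `params` (named estimates),
#'   `covariance`, `loglik`, `n_points`, `k`, `t1`, `t2`, `variant`,
#'   `model_end` and the underlying `lm` fit.
#' @export
fit_lactation <- function(curve, variant = c("alping_full", "alping_truncated", "wilmink"),
                          k = 0.1, t1 = NULL, t2 = NULL, model_end = NULL,
                          refine = FALSE) {
  variant <- match.arg(variant)
  if (is.null(t1)) t1 <- attr(curve, "t1")
  if (is.null(t2)) t2 <- attr(curve, "t2")
  pts <- as.data.frame(curve)
  if (!nrow(pts)) stop("empty curve", call. = FALSE)
  if (refine && variant == "alping_full") {
    tt <- refine_transitions(curve, k = k, t1 = t1, t2 = t2)
    t1 <- tt["t1"]; t2 <- tt["t2"]
  }
  if (is.null(model_end)) {
    model_end <- if (variant == "alping_truncated") t2 else 500
  }
  pts <- pts[pts$dim <= model_end, , drop = FALSE]
  X <- design_matrix(pts$dim, k = k, t1 = t1, t2 = t2, variant = variant)
  .wls_fit(X, pts$mean_yield, pts$weight, k = k, t1 = t1, t2 = t2,
           variant = variant, model_end = model_end)
}

# shared WLS core; X must have named columns
.wls_fit <- function(X, y, w, k, t1, t2, variant, model_end) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("singular design: column(s) %s are collinear with the others",
                 paste(dep, collapse = ", ")), call. = FALSE)
  }
  if (nrow(X) < ncol(X)) {
    stop(sprintf("%d points cannot identify %d parameters", nrow(X), ncol(X)),
         call. = FALSE)
  }
  dat <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~ 0 +", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- stats::lm(fml, data = dat, weights = w)
  params <- stats::setNames(coef(fit), colnames(X))
  covariance <- vcov(fit)
  dimnames(covariance) <- list(colnames(X), colnames(X))
  structure(list(params = params,
                 covariance = covariance,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_points = nrow(X),
                 k = k, t1 = t1, t2 = t2,
                 variant = variant, model_end = model_end,
                 lm = fit),
            class = "lactation_fit")
}

#' @export
print.lactation_fit <- function(x, ...) {
  cat(sprintf("<lactation_fit> variant '%s', k = %g, %d points, horizon %g DIM\n",
              x$variant, x$k, x$n_points, x$model_end))
  if (!is.null(x$t1) && !is.na(x$t1)) {
    cat(sprintf("  alping t1 = %g, t2 = %s\n", x$t1,
                if (is.null(x$t2) || is.na(x$t2)) "-" else format(x$t2)))
  }
  se <- sqrt(diag(x$covariance))
  est <- format(signif(x$params, 4))
  cat("  parameters (kg, kg, kg/day, ...):\n")
  for (i in seq_along(x$params)) {
    cat(sprintf("    %s = %s (se %s)\n", names(x$params)[i], est[i],
                format(signif(se[i], 3))))
  }
  cat(sprintf("  logLik = %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.lactation_fit <- function(object, ...) object$params

#' @export
vcov.lactation_fit <- function(object, ...) object$covariance

#' @export
logLik.lactation_fit <- function(object, ...) {
  stats::logLik(object$lm)
}

#' Predicted yield of a fitted lactation curve
#' @param object a `lactation_fit`.
#' @param t DIM values to predict at.
#' @param ... unused.
#' @return predicted yields, kg.
#' @export
predict.lactation_fit <- function(object, t, ...) {
  X <- design_matrix(t, k = object$k, t1 = object$t1, t2 = object$t2,
                     variant = object$variant)
  drop(X %*% object$params)
}

#' Approximate milk lost to alping
#'
#' The fitted alping slope `d` (kg/day) accumulated over `x` days:
#' `|d| x^2 / 2`, reported as a positive loss in kg. Quadratic in the
#' duration: doubling `x` quadruples the loss.
#'
#' @param d alping slope, kg/day (typically negative).
#' @param x duration in days (>= 0).
#' @return lost milk, kg.
#' @export
milk_loss <- function(d, x) {
  if (any(x < 0)) stop("duration x must be >= 0", call. = FALSE)
  abs(d) * x^2 / 2
}

#' Closed-form production integral of a fitted curve
#'
#' Integrates the fitted piecewise curve over `[t_start, t_end]` in kg:
#' the exponential term integrates to `-b/k exp(-k t)`, the linear and hinge
#' terms to quadratics, and the boost term contributes `f` times the length
#' of overlap of the interval with `(t2, t_end]`.
#'
#' @param fit a `lactation_fit`.
#' @param t_start,t_end integration bounds in DIM, with
#'   `0 <= t_start < t_end <= model_end`.
#' @return production in kg.
#' @export
integrate_production <- function(fit, t_start, t_end) {
  if (!(t_start < t_end)) stop("t_start must be < t_end", call. = FALSE)
  if (t_start < 0 || t_end > fit$model_end) {
    stop(sprintf("integration interval [%g, %g] outside the fitting horizon [0, %g]",
                 t_start, t_end, fit$model_end), call. = FALSE)
  }
  p <- fit$params[c("a", "b", "c", "d", "f", "g")]
  p[is.na(p)] <- 0
  names(p) <- c("a", "b", "c", "d", "f", "g")
  k <- fit$k
  hinge_int <- function(knot) {
    (max(0, t_end - knot)^2 - max(0, t_start - knot)^2) / 2
  }
  total <- p["a"] * (t_end - t_start) +
    p["b"] * (exp(-k * t_start) - exp(-k * t_end)) / k +
    p["c"] * (t_end^2 - t_start^2) / 2
  if (!is.null(fit$t1) && !is.na(fit$t1)) total <- total + p["d"] * hinge_int(fit$t1)
  if (!is.null(fit$t2) && !is.na(fit$t2)) {
    total <- total + p["g"] * hinge_int(fit$t2) +
      p["f"] * max(0, t_end - max(t_start, fit$t2))
  }
  unname(total)
}

#' Refine alping transitions on the fitted-model objective
#'
#' Record-based transition estimates carry up-to-a-day uncertainty from the
#' monthly sampling; because the post-return boost is a 0/1 step, even a
#' half-day error in `t2` is absorbed into the boost height. This profiles
#' the weighted SSE of the full model over candidate knots around the
#' starting values — a standard changepoint refinement. `t2` is profiled on
#' whole days (the step indicator only changes at integers; within a unit
#' cell the `f`/`g` trade-off makes the SSE exactly invariant) and `t1` on
#' half days.
#'
#' @param curve an `averaged_curve` with starting `t1`/`t2` attributes (or
#'   pass `t1`, `t2`).
#' @param k fixed decay constant.
#' @param t1,t2 starting values (default: the curve's attributes).
#' @param span search half-width in days (default 8).
#' @return `c(t1 = , t2 = )`, the SSE-minimising knots.
#' @export
refine_transitions <- function(curve, k = 0.1, t1 = attr(curve, "t1"),
                               t2 = attr(curve, "t2"), span = 8) {
  pts <- as.data.frame(curve)
  sse <- function(tt1, tt2) {
    X <- design_matrix(pts$dim, k = k, t1 = tt1, t2 = tt2, variant = "alping_full")
    f <- stats::lm.wfit(X, pts$mean_yield, pts$weight)
    sum(pts$weight * f$residuals^2)
  }
  t1_cand <- seq(t1 - span, t1 + span, by = 0.5)
  t2_cand <- seq(floor(t2) - span, floor(t2) + span, by = 1)
  grid <- expand.grid(t1 = t1_cand, t2 = t2_cand)
  grid <- grid[grid$t1 < grid$t2 - 1, , drop = FALSE]
  vals <- mapply(sse, grid$t1, grid$t2)
  best <- grid[which.min(vals), ]
  c(t1 = best$t1, t2 = best$t2)
}

#' Estimate the exponential decay constant k
#'
#' Profile search: for each candidate `k` the remaining parameters are
#' refitted by WLS; a coarse grid over `[0.01, 0.5]` is refined by
#' golden-section search around the grid minimum of the weighted SSE. With no
#' identifiable rising phase (`b` near 0, flat profile) a warning is issued
#' and the conventional default 0.1 returned.
#'
#' @param curve an `averaged_curve` with at least 10 points.
#' @param variant model variant (default follows the curve's transitions).
#' @param k_range search interval (default `c(0.01, 0.5)`).
#' @return the estimated `k`, 1/day.
#' @export
estimate_k <- function(curve, variant = NULL, k_range = c(0.01, 0.5)) {
  pts <- as.data.frame(curve)
  if (nrow(pts) < 10) stop("need at least 10 curve points to profile k", call. = FALSE)
  t1 <- attr(curve, "t1"); t2 <- attr(curve, "t2")
  if (is.null(variant)) {
    variant <- if (!is.null(t1) && !is.na(t1)) "alping_full" else "wilmink"
  }
  sse <- function(k) {
    X <- design_matrix(pts$dim, k = k, t1 = t1, t2 = t2, variant = variant)
    f <- stats::lm.wfit(X, pts$mean_yield, pts$weight)
    sum(pts$weight * f$residuals^2)
  }
  grid <- seq(k_range[1], k_range[2], length.out = 50)
  vals <- vapply(grid, sse, numeric(1))
  if (diff(range(vals)) <= 1e-10 * (1 + mean(vals))) {
    warning("flat k-profile (no identifiable rising phase); returning default 0.1")
    return(0.1)
  }
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi))
  k_hat <- opt$minimum
  X <- design_matrix(pts$dim, k = k_hat, t1 = t1, t2 = t2, variant = variant)
  b_hat <- stats::lm.wfit(X, pts$mean_yield, pts$weight)$coefficients["b"]
  if (!is.finite(b_hat) || abs(b_hat) < 1e-6) {
    warning("rising-phase coefficient b is ~0; k unidentifiable, returning default 0.1")
    return(0.1)
  }
  k_hat
}
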