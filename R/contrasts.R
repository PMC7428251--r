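## Tertile-based two-group factor contrasts.
##
## A factor (environmental, physiological or morphological) splits a
## calving-month cohort into two contrasted groups — bottom vs top tertile,
## or middle vs top tertile for the heat/cold indices, where production is
## best under mild conditions. Each group's averaged curve is stacked with
## the other's and a joint weighted model is fitted in which the chosen
## parameters carry a 0/1 dummy-interaction column; the null model omits all
## interactions. The likelihood-ratio statistic G = 2 (ll_alt - ll_null) is
## referred to a chi-square with one df per interaction.
##
## Environmental factors act only during the alp stay: the curve is modelled
## only until the end of the alping season (f and g are not estimated) and
## only d varies between groups. Physiological and morphological factors act
## over the whole cycle: all six parameters may vary.

#' Describe a contrast factor
#'
#' @param name factor label.
#' @param category `"environmental"`, `"physiological"` or
#'   `"morphological"`. Environmental factors imply `horizon =
#'   "alping_only"` and `vary_params = "d"`; the other categories imply the
#'   full lactation horizon with all six parameters free to vary.
#' @param value_fn a function `function(dataset)` returning the factor value
#'   per lactation (in `dataset$lactations` order) for lactation-level
#'   factors, or per record (in `dataset$records` order, `NA` off-alp) when
#'   `level = "record"`. `dataset` is a list with `records`, `lactations`,
#'   `cows`, `alps` and, when supplied, `exposure`.
#' @param grouping `"t1_vs_t3"` (bottom vs top tertile), `"t2_vs_t3"`
#'   (middle vs top, the THI/CSI convention) or `"explicit"` (the value
#'   function returns group labels directly, e.g. a biogeographic region).
#' @param level `"lactation"` (default) or `"record"`; climate indices are
#'   record-level (the exposure at that test day), all other factors
#'   lactation-level.
#' @return a `factor_spec`.
#' @export
factor_spec <- function(name, category = c("environmental", "physiological",
                                           "morphological"),
                        value_fn, grouping = c("t1_vs_t3", "t2_vs_t3", "explicit"),
                        level = c("lactation", "record")) {
  category <- match.arg(category)
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  spec <- list(name = name, category = category, value_fn = value_fn,
               grouping = grouping, level = level)
  if (category == "environmental") {
    spec$horizon <- "alping_only"
    spec$vary_params <- "d"
  } else {
    spec$horizon <- "full_lactation"
    spec$vary_params <- c("a", "b", "c", "d", "f", "g")
  }
  structure(spec, class = "factor_spec")
}

.contrast_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("alpcurve_contrast_infeasible", "error")))
}

#' Split values into two contrasted groups
#'
#' Tertile modes use the 1/3 and 2/3 quantiles of the non-missing values:
#' `"t1_vs_t3"` contrasts values strictly below the first cutoff with values
#' strictly above the second (middle third excluded); `"t2_vs_t3"` contrasts
#' values strictly between the cutoffs with values strictly above the second.
#' `"explicit"` takes the values themselves as group labels (exactly two
#' levels required).
#'
#' @param values numeric factor values (or labels for `"explicit"`).
#' @param grouping see [factor_spec()].
#' @return a list with `labels` (character, `NA` for excluded members,
#'   ordered so the first level is the lower/middle group) and `cutoffs`
#'   (`c(NA, NA)` for explicit grouping).
#' @export
assign_groups <- function(values, grouping = c("t1_vs_t3", "t2_vs_t3", "explicit")) {
  grouping <- match.arg(grouping)
  if (grouping == "explicit") {
    lev <- sort(unique(stats::na.omit(as.character(values))))
    if (length(lev) != 2) {
      .contrast_infeasible(sprintf("explicit grouping needs exactly 2 levels, found %d",
                                   length(lev)))
    }
    return(list(labels = as.character(values), levels = lev,
                cutoffs = c(NA_real_, NA_real_), grouping = grouping))
  }
  v <- values[!is.na(values)]
  if (length(unique(v)) < 3) {
    .contrast_infeasible("tertile grouping needs at least 3 distinct values")
  }
  q <- stats::quantile(v, c(1/3, 2/3), names = FALSE, type = 7)
  lab <- rep(NA_character_, length(values))
  if (grouping == "t1_vs_t3") {
    lab[!is.na(values) & values < q[1]] <- "t1"
    lab[!is.na(values) & values > q[2]] <- "t3"
    lev <- c("t1", "t3")
  } else {
    lab[!is.na(values) & values > q[1] & values < q[2]] <- "t2"
    lab[!is.na(values) & values > q[2]] <- "t3"
    lev <- c("t2", "t3")
  }
  if (length(unique(stats::na.omit(lab))) < 2) {
    .contrast_infeasible("fewer than 2 non-empty groups after tertile split")
  }
  list(labels = lab, levels = lev, cutoffs = q, grouping = grouping)
}

#' Bonferroni correction
#'
#' `min(1, m p)` per p-value; `m` defaults to the number of tests supplied
#' but is conventionally the full family size (factors x calving months).
#'
#' @param p p-values in `[0, 1]`.
#' @param m family size.
#' @return adjusted p-values, order preserved, elementwise `>= p`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, p * m)
}

# build the stacked two-group curve table for the joint fit, from a dataset
# already restricted to the calving-month cohort.
# returns data.frame(dim, y, w, part) with part in {group levels} plus
# "base" for the shared lowland baseline of record-level (climate) factors.
.stacked_curves <- function(spec, cohort, cm, labels, alping_window, response) {
  rec <- cohort$records
  lact <- cohort$lactations
  if (spec$level == "record") {
    ## per-record membership: alp records split by group, lowland shared
    in_win <- .in_alping_window(rec$record_date, alping_window)
    eligible <- (in_win & rec$site == "alp") | (!in_win & rec$site == "lowland")
    rec <- rec[eligible, , drop = FALSE]
    labels <- labels[eligible]
    dim_ <- .dim_of(rec$record_date,
                    lact$calving_date[match(rec$lactation_id, lact$lactation_id)])
    is_alp <- rec$site == "alp"
    part <- ifelse(is_alp, labels, "base")
    ok <- !is_alp | !is.na(labels)
    if (!any(ok & is_alp)) .contrast_infeasible("no grouped alp records in cohort")
    dt <- data.table::data.table(dim_ = dim_[ok], y = rec[[response]][ok],
                                 part = part[ok])
    agg <- dt[, .(mean_yield = mean(y), n_obs = .N), by = .(part, dim_)]
    out <- data.frame(dim = agg$dim_, y = agg$mean_yield, w = as.numeric(agg$n_obs),
                      part = agg$part)
  } else {
    ## per-lactation membership: one full curve per group
    out <- NULL
    for (g in unique(stats::na.omit(labels))) {
      lids <- lact$lactation_id[!is.na(labels) & labels == g]
      sub_l <- lact[lact$lactation_id %in% lids, , drop = FALSE]
      sub_r <- rec[rec$lactation_id %in% lids, , drop = FALSE]
      if (!nrow(sub_r)) .contrast_infeasible(sprintf("group '%s' has no records", g))
      cv <- tryCatch(
        build_curve(sub_r, sub_l, cm, alping_window = alping_window,
                    response = response,
                    transitions = c(t1 = NA_real_, t2 = NA_real_)),
        error = function(e) .contrast_infeasible(conditionMessage(e)))
      out <- rbind(out, data.frame(dim = cv$dim, y = cv$mean_yield,
                                   w = cv$weight, part = g))
    }
  }
  out
}

#' Two-group contrast of an influencing factor
#'
#' Builds the per-group averaged curves of one calving-month cohort, fits
#' the joint dummy-interaction model against the no-interaction null,
#' integrates per-group production, and reports percent differences, the
#' d-parameter gap and the Bonferroni-corrected G-test. Factor values,
#' tertile cutoffs and group membership are all evaluated within the cohort
#' being contrasted, so both groups are guaranteed to draw from the same
#' calving month.
#'
#' The reference group is the one with the highest production during alping;
#' percent differences are `(other - ref)/ref * 100` and
#' `delta_d = d_ref - d_other` (positive: the reference is less impacted by
#' alping).
#'
#' @param spec a [factor_spec()].
#' @param dataset herd list (`records`, `lactations`, `cows`, `alps`),
#'   QC-filtered; for record-level climate factors add an `exposure` element
#'   from [compute_exposure()] (its `thi`/`csi` columns are what `value_fn`
#'   typically reads).
#' @param calving_month month number or name.
#' @param k fixed decay constant.
#' @param alping_window calendar alping window, as in [build_curve()].
#' @param m family size for the Bonferroni correction.
#' @param response trait column to analyse.
#' @return a `contrast_result` with the per-group fits, production
#'   integrals, `pct_diff_alping`, `pct_diff_total` (full-lactation factors
#'   only), `delta_d`, `delta_d_se`, `g_stat`, `df`, `p_raw`, `p_bonferroni`.
#' @export
contrast_factor <- function(spec, dataset, calving_month, k = 0.1,
                            alping_window = c("05-15", "08-31"), m = 1,
                            response = "milk_kg") {
  stopifnot(inherits(spec, "factor_spec"))
  cm <- .month_num(calving_month)

  ## restrict to the calving-month cohort first: factor values, tertile
  ## cutoffs and group membership are all cohort-level
  lact <- as.data.frame(dataset$lactations)
  lact <- lact[as.integer(format(lact$calving_date, "%m")) == cm, , drop = FALSE]
  rec <- as.data.frame(dataset$records)
  rec <- rec[rec$lactation_id %in% lact$lactation_id, , drop = FALSE]
  if (!nrow(rec)) .contrast_infeasible(sprintf("no records for calving month %s",
                                               month.abb[cm]))
  cohort <- list(records = rec, lactations = lact,
                 cows = dataset$cows, alps = dataset$alps)
  if (!is.null(dataset$exposure)) cohort$exposure <- dataset$exposure
  values <- spec$value_fn(cohort)
  grp <- assign_groups(values, spec$grouping)
  labels <- grp$labels

  ## pooled cohort transitions shared by both groups
  trans <- locate_transitions(cohort$records, cohort$lactations, cm)
  t1 <- trans["t1"]; t2 <- trans["t2"]

  stacked <- .stacked_curves(spec, cohort, cm, labels, alping_window, response)
  lev <- grp$levels
  present <- intersect(lev, unique(stacked$part))
  if (length(present) < 2) .contrast_infeasible("empty group after record selection")
  stacked$grp <- ifelse(stacked$part == lev[2], 1, 0)

  env <- spec$horizon == "alping_only"
  variant <- if (env) "alping_truncated" else "alping_full"
  model_end <- if (env) unname(t2) else 500
  stacked <- stacked[stacked$dim <= model_end, , drop = FALSE]

  Xb <- design_matrix(stacked$dim, k = k, t1 = t1, t2 = t2, variant = variant)
  vary <- intersect(spec$vary_params, colnames(Xb))
  Xi <- Xb[, vary, drop = FALSE] * stacked$grp
  colnames(Xi) <- paste0(vary, ":grp")

  null_fit <- .wls_fit(Xb, stacked$y, stacked$w, k, t1, t2, variant, model_end)
  alt_fit <- .wls_fit(cbind(Xb, Xi), stacked$y, stacked$w, k, t1, t2, variant, model_end)

  g_stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  df <- length(vary)
  p_raw <- stats::pchisq(g_stat, df = df, lower.tail = FALSE)

  ## per-group parameter sets from the joint fit
  base <- alt_fit$params[colnames(Xb)]
  inter <- alt_fit$params[colnames(Xi)]
  p1 <- base
  p2 <- base
  p2[vary] <- p2[vary] + inter
  mk_fit <- function(p) {
    structure(list(params = p, covariance = NULL, loglik = NA_real_,
                   n_points = alt_fit$n_points, k = k, t1 = unname(t1),
                   t2 = unname(t2), variant = variant, model_end = model_end),
              class = "lactation_fit")
  }
  fits <- list(mk_fit(p1), mk_fit(p2))
  names(fits) <- lev

  alp_lo <- unname(t1); alp_hi <- min(unname(t2), model_end)
  prod_alp <- vapply(fits, integrate_production, numeric(1), t_start = alp_lo,
                     t_end = alp_hi)
  ref_i <- which.max(prod_alp)
  oth_i <- 3 - ref_i
  pct_alp <- (prod_alp[oth_i] - prod_alp[ref_i]) / prod_alp[ref_i] * 100
  if (!env) {
    prod_tot <- vapply(fits, integrate_production, numeric(1), t_start = 5,
                       t_end = model_end)
    pct_tot <- (prod_tot[oth_i] - prod_tot[ref_i]) / prod_tot[ref_i] * 100
  } else {
    prod_tot <- c(NA_real_, NA_real_)
    pct_tot <- NA_real_
  }

  d1 <- p1["d"]; d2 <- p2["d"]
  delta_d <- unname(if (ref_i == 1) d1 - d2 else d2 - d1)
  dd_se <- if ("d:grp" %in% colnames(Xi)) sqrt(alt_fit$covariance["d:grp", "d:grp"]) else NA_real_

  structure(list(factor = spec, calving_month = cm,
                 cutoffs = grp$cutoffs, groups = lev,
                 reference_group = lev[ref_i],
                 fits = fits, joint_fit = alt_fit, null_fit = null_fit,
                 production_alping = prod_alp, production_total = prod_tot,
                 pct_diff_alping = unname(pct_alp), pct_diff_total = unname(pct_tot),
                 delta_d = delta_d, delta_d_se = unname(dd_se),
                 g_stat = unname(g_stat), df = df,
                 p_raw = unname(p_raw),
                 p_bonferroni = unname(bonferroni(p_raw, m))),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s (%s), calving month %s\n",
              x$factor$name, x$factor$category, month.abb[x$calving_month]))
  if (!all(is.na(x$cutoffs))) {
    cat(sprintf("  cutoffs: %.4g / %.4g; groups %s vs %s (reference: %s)\n",
                x$cutoffs[1], x$cutoffs[2], x$groups[1], x$groups[2],
                x$reference_group))
  } else {
    cat(sprintf("  groups %s vs %s (reference: %s)\n", x$groups[1], x$groups[2],
                x$reference_group))
  }
  cat(sprintf("  production during alping: %s kg\n",
              paste(sprintf("%s = %.0f", names(x$production_alping),
                            x$production_alping), collapse = ", ")))
  cat(sprintf("  pct diff (alping) = %.2f%%", x$pct_diff_alping))
  if (!is.na(x$pct_diff_total)) cat(sprintf(", (total) = %.2f%%", x$pct_diff_total))
  cat("\n")
  cat(sprintf("  delta_d = %.4f kg/day (se %.4f)\n", x$delta_d, x$delta_d_se))
  cat(sprintf("  G = %.3f on %d df, p = %.3g (Bonferroni %.3g)\n",
              x$g_stat, x$df, x$p_raw, x$p_bonferroni))
  invisible(x)
}

#' Flatten contrast results to a table
#' @param results a list of `contrast_result`s.
#' @return a data.frame, one row per contrast.
#' @export
contrast_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(factor = x$factor$name, category = x$factor$category,
               month = month.abb[x$calving_month],
               cutoff_low = x$cutoffs[1], cutoff_high = x$cutoffs[2],
               ref_group = x$reference_group,
               pct_diff_alping = x$pct_diff_alping,
               pct_diff_total = x$pct_diff_total,
               delta_d = x$delta_d, g_stat = x$g_stat, df = x$df,
               p_raw = x$p_raw, p_bonf = x$p_bonferroni,
               row.names = NULL)
  }))
}
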