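## Per-calving-month averaged lactation curves.
##
## Monthly test-day records are too sparse to fit per cow, so the fitting
## unit is the cohort: for every DIM, the mean of all eligible records of the
## calving-month cohort, weighted by the number of observations. During the
## calendar alping window only alp records are eligible (cows still in the
## lowland would otherwise dilute the alping signal); outside it only
## lowland records are.

.month_num <- function(m) {
  if (is.numeric(m)) return(as.integer(m))
  i <- match(tolower(substr(m, 1, 3)), tolower(month.abb))
  if (is.na(i)) stop("unknown calving month: ", m, call. = FALSE)
  i
}

.in_alping_window <- function(dates, window = c("05-15", "08-31")) {
  md <- format(dates, "%m-%d")
  md >= window[1] & md <= window[2]
}

#' Locate the cohort's alp ascent and return DIM
#'
#' Determined independently for each calving-month cohort, as the median
#' over lactations of a per-lactation estimate:
#'
#' * `"midpoint"` (default): the centre of the admissible transition-day
#'   interval implied by the records that bracket the site change (the
#'   ascent lies between the last lowland record and the first alp record,
#'   the return between the last alp record and the next record). Under
#'   ~30-day test-day sampling the first alp record falls up to a month
#'   after the true ascent, so the plain first-alp-record DIM is late by
#'   half the sampling interval on average; the bracket centre removes
#'   that bias.
#' * `"observed"`: the DIM of the first/last alp record itself.
#' * `"calendar"`: the DIM at which a fixed calendar alping window
#'   (15 May / 31 Aug) falls for each lactation, ignoring the records.
#'
#' @param records,lactations herd tables (QC-filtered).
#' @param calving_month month number (1--12) or name.
#' @param mode transition estimator, see above.
#' @param alping_window calendar window used by `mode = "calendar"`.
#' @return a named numeric vector `c(t1 = , t2 = )`.
#' @export
locate_transitions <- function(records, lactations, calving_month,
                               mode = c("midpoint", "observed", "calendar"),
                               alping_window = c("05-15", "08-31")) {
  mode <- match.arg(mode)
  cm <- .month_num(calving_month)
  lact <- as.data.frame(lactations)
  lact <- lact[as.integer(format(lact$calving_date, "%m")) == cm, , drop = FALSE]
  rec <- as.data.frame(records)
  rec <- rec[rec$lactation_id %in% lact$lactation_id, , drop = FALSE]
  if (!any(rec$site == "alp")) {
    stop(sprintf("no alp records for calving month %s; transitions undefined",
                 month.abb[cm]), call. = FALSE)
  }
  rec$dim_ <- .dim_of(rec$record_date,
                      lact$calving_date[match(rec$lactation_id, lact$lactation_id)])
  if (mode == "calendar") {
    lids <- unique(rec$lactation_id[rec$site == "alp"])
    cal <- lact$calving_date[match(lids, lact$lactation_id)]
    yr <- as.integer(format(cal, "%Y"))
    asc <- as.Date(sprintf("%d-%s", yr, alping_window[1]))
    nxt <- asc <= cal
    asc[nxt] <- as.Date(sprintf("%d-%s", yr[nxt] + 1L, alping_window[1]))
    ret <- as.Date(sprintf("%s-%s", format(asc, "%Y"), alping_window[2]))
    t1 <- stats::median(as.numeric(asc - cal))
    t2 <- stats::median(as.numeric(ret - cal))
  } else {
    per_lact <- lapply(split(rec[, c("dim_", "site")], rec$lactation_id), function(x) {
      alp <- sort(x$dim_[x$site == "alp"])
      if (!length(alp)) return(NULL)
      all_d <- sort(x$dim_)
      if (mode == "observed") return(c(min(alp), max(alp)))
      before <- all_d[all_d < min(alp)]
      after <- all_d[all_d > max(alp)]
      ## only bracketed transitions enter the medians: a lactation whose
      ## records start on the alp or end there (dry-off) carries no
      ## information about when the herd moved. The ascent day lies in
      ## {prev+1, ..., first_alp} and the return day in
      ## {last_alp, ..., next-1}, so the conditional means carry a half-day
      ## shift relative to the naive midpoints.
      c(if (length(before)) (min(alp) + max(before) + 1) / 2 else NA_real_,
        if (length(after)) (max(alp) + min(after)) / 2 else NA_real_)
    })
    per_lact <- do.call(rbind, per_lact)
    t1 <- stats::median(per_lact[, 1], na.rm = TRUE)
    t2 <- stats::median(per_lact[, 2], na.rm = TRUE)
    if (is.na(t1)) t1 <- stats::median(vapply(split(rec$dim_[rec$site == "alp"],
                                                    rec$lactation_id[rec$site == "alp"]),
                                              min, numeric(1)))
    if (is.na(t2)) t2 <- stats::median(vapply(split(rec$dim_[rec$site == "alp"],
                                                    rec$lactation_id[rec$site == "alp"]),
                                              max, numeric(1)))
  }
  if (!(t1 < t2)) {
    stop(sprintf("degenerate alping transitions (t1 = %g, t2 = %g)", t1, t2),
         call. = FALSE)
  }
  c(t1 = unname(t1), t2 = unname(t2))
}

#' Build the averaged daily curve of a calving-month cohort
#'
#' For each DIM, the mean and count of eligible test-day yields. Eligibility:
#' inside the calendar alping window (default 15 May -- 31 Aug, any year)
#' only `site = "alp"` records enter the mean; outside it only
#' `site = "lowland"` records. Point weights start equal to the observation
#' counts; see [reweight_pre_alping()].
#'
#' @param records,lactations herd tables (QC-filtered).
#' @param calving_month month number (1--12) or name.
#' @param alping_window character `c("mm-dd", "mm-dd")` calendar window.
#' @param response column of `records` to average (default `"milk_kg"`; any
#'   numeric trait column works).
#' @param transitions optional `c(t1=, t2=)` override; by default
#'   [locate_transitions()] is used when the cohort has alp records.
#' @param transition_mode estimator passed to [locate_transitions()].
#' @return an `averaged_curve`: a data.frame with columns `dim`,
#'   `mean_yield`, `n_obs`, `weight` and attributes `calving_month`, `t1`,
#'   `t2`.
#' @export
build_curve <- function(records, lactations, calving_month,
                        alping_window = c("05-15", "08-31"),
                        response = "milk_kg", transitions = NULL,
                        transition_mode = "midpoint") {
  cm <- .month_num(calving_month)
  lact <- as.data.frame(lactations)
  lact <- lact[as.integer(format(lact$calving_date, "%m")) == cm, , drop = FALSE]
  rec <- as.data.frame(records)
  rec <- rec[rec$lactation_id %in% lact$lactation_id, , drop = FALSE]
  if (!nrow(rec)) {
    stop(sprintf("no records for calving month %s", month.abb[cm]), call. = FALSE)
  }
  in_win <- .in_alping_window(rec$record_date, alping_window)
  eligible <- (in_win & rec$site == "alp") | (!in_win & rec$site == "lowland")
  rec <- rec[eligible, , drop = FALSE]
  if (!nrow(rec)) {
    stop(sprintf("no eligible records for calving month %s", month.abb[cm]),
         call. = FALSE)
  }
  dim_ <- .dim_of(rec$record_date,
                  lact$calving_date[match(rec$lactation_id, lact$lactation_id)])
  y <- rec[[response]]
  dt <- data.table::data.table(dim_ = dim_, y = y)
  pts <- dt[, .(mean_yield = mean(y), n_obs = .N), by = dim_][order(dim_)]
  if (is.null(transitions)) {
    transitions <- tryCatch(
      locate_transitions(records, lactations, cm, mode = transition_mode,
                         alping_window = alping_window),
      error = function(e) c(t1 = NA_real_, t2 = NA_real_))
  }
  curve <- data.frame(dim = pts$dim_, mean_yield = pts$mean_yield,
                      n_obs = pts$n_obs, weight = as.numeric(pts$n_obs))
  structure(curve, class = c("averaged_curve", "data.frame"),
            calving_month = cm,
            t1 = unname(transitions["t1"]), t2 = unname(transitions["t2"]))
}

#' Up-weight the pre-alping part of a curve
#'
#' Multiplies the weights of points with `dim < t1` by `multiplier`
#' (conventionally 100), so a fit anchors the early curve tightly before the
#' alping slope is read off; the boundary point at `dim = t1` belongs to
#' alping and is left unchanged.
#'
#' @param curve an `averaged_curve` with `t1` set.
#' @param multiplier weight multiplier (default 100).
#' @return the reweighted curve.
#' @export
reweight_pre_alping <- function(curve, multiplier = 100) {
  t1 <- attr(curve, "t1")
  if (is.null(t1) || is.na(t1)) {
    stop("curve has no alp-ascent DIM (t1); cannot reweight", call. = FALSE)
  }
  curve$weight <- ifelse(curve$dim < t1, curve$weight * multiplier, curve$weight)
  curve
}

#' @export
print.averaged_curve <- function(x, ...) {
  cat(sprintf("<averaged_curve> calving month %s: %d daily points, DIM %d..%d, %d observations\n",
              month.abb[attr(x, "calving_month")], nrow(x),
              min(x$dim), max(x$dim), sum(x$n_obs)))
  t1 <- attr(x, "t1"); t2 <- attr(x, "t2")
  if (!is.na(t1)) cat(sprintf("  alping: t1 = %g, t2 = %g (DIM)\n", t1, t2))
  invisible(x)
}

#' Write / read an averaged curve as CSV
#' @param curve an `averaged_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  df$calving_month <- attr(curve, "calving_month")
  df$t1 <- attr(curve, "t1"); df$t2 <- attr(curve, "t2")
  utils::write.csv(df[, c("calving_month", "dim", "mean_yield", "n_obs",
                          "weight", "t1", "t2")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  structure(df[, c("dim", "mean_yield", "n_obs", "weight")],
            class = c("averaged_curve", "data.frame"),
            calving_month = df$calving_month[1],
            t1 = df$t1[1], t2 = df$t2[1])
}
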