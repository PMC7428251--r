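## Quality-control cascade for test-day herd data.
##
## Fourteen rules, applied in the listed order; an entity failing several
## rules is counted once, at the first rule that removes it. Removing a cow
## cascades to its lactations and records; removing a lactation cascades to
## its records. The report tracks both the count at the rule's own level and
## the cascaded counts at every level, so that at each level
## n_input = n_surviving + sum(removed).

.qc_rules <- data.frame(
  rule_id = c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x",
              "xi", "xii", "xiii", "xiv"),
  level = c("record", "cow", "cow", "cow", "cow", "lactation", "lactation",
            "lactation", "lactation", "lactation", "lactation", "lactation",
            "record", "record"),
  description = c(
    "record outside the complete-year window",
    "mean first-to-last insemination interval > threshold over first lactations",
    "age at first calving outside the allowed range",
    "breed other than (Original) Braunvieh",
    "sire or dam breed other than (Original) Braunvieh",
    "lactation shorter than the minimum observed length",
    "calving interval below the minimum",
    "alp altitude outside the allowed band",
    "calving in an excluded month",
    "parity above the maximum",
    "first record taken too late after calving",
    "record(s) taken before calving",
    "record DIM outside the valid window",
    "second alping season within one lactation"),
  stringsAsFactors = FALSE)

#' Default thresholds for the quality-control cascade
#'
#' Returns the full threshold set with conventional defaults: a complete-year
#' date window, a 100-day cap on the mean first-to-last insemination interval
#' (over the first three lactations), first calving between 2 and 4 years of
#' age, (Original) Braunvieh breed codes, 270-day minimum lactation, 290-day
#' minimum calving interval, alp altitudes in 1100--2600 m, calvings in
#' March--August excluded, parity at most 9, first record by DIM 42, and the
#' valid record window DIM 5--500.
#'
#' @param ... named overrides of any default listed above.
#' @return a named list of thresholds.
#' @export
qc_config <- function(...) {
  cfg <- list(
    date_range = as.Date(c("2000-07-01", "2015-06-30")),
    max_insemination_interval = 100,     # days, mean over first lactations
    n_insemination_lactations = 3,
    first_calving_age_years = c(2, 4),
    breeds = c("Braunvieh", "Original Braunvieh"),
    min_lactation_days = 270,
    min_calving_interval = 290,
    alp_altitude_range = c(1100, 2600),
    excluded_calving_months = 3:8,       # March .. August
    max_parity = 9,
    max_first_record_dim = 42,
    dim_range = c(5, 500)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown qc_config option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg$date_range <- as.Date(cfg$date_range)
  cfg
}

# identify records in a second (or later) maximal alp run, per lactation.
# x: data.table with lactation_id, dim_, site, already restricted to the
# records the runs should be computed on; returns row indices (into x).
.second_alp_run_idx <- function(x) {
  if (!nrow(x)) return(integer(0))
  ord <- order(x$lactation_id, x$dim_)
  lid <- x$lactation_id[ord]
  alp <- x$site[ord] == "alp"
  new_lact <- c(TRUE, lid[-1] != lid[-length(lid)])
  # run starts: first alp record of each maximal alp run
  run_start <- alp & (new_lact | c(FALSE, !alp[-length(alp)]))
  run_no <- ave(as.integer(run_start), lid, FUN = cumsum)
  ord[alp & run_no >= 2]
}

# records eligible for span-based rules: inside the DIM window and not in a
# second alping run (so the cascade has a fixpoint; see methods vignette)
.span_records <- function(rec, cfg) {
  keep <- !is.na(rec$dim_) & rec$dim_ >= cfg$dim_range[1] & rec$dim_ <= cfg$dim_range[2]
  sub <- rec[keep, c("lactation_id", "dim_", "site")]
  second <- .second_alp_run_idx(sub)
  if (length(second)) keep[which(keep)[second]] <- FALSE
  rec[keep, c("lactation_id", "dim_")]
}

#' Apply the quality-control cascade
#'
#' Applies the fourteen filtering rules in order, with sequential removal
#' accounting: an entity violating several rules is counted at the first.
#' Cow-level removals cascade to the cow's lactations and records;
#' lactation-level removals cascade to records. Rules vi (lactation length)
#' and xi (first-record DIM) are evaluated on the records that survive the
#' record-level DIM window and second-alping-run trim, which makes the
#' cascade idempotent: re-applying it to its own output removes nothing.
#'
#' @param records,lactations,cows,alps herd tables as returned by
#'   [read_records()] and friends (or [simulate_herd()]).
#' @param config thresholds from [qc_config()].
#' @return a list with the surviving `records`, `lactations`, `cows`, `alps`
#'   (alps are never filtered) and `report`, a data.frame with one row per
#'   rule: `rule_id`, `description`, `level`, `n_removed` (count at the
#'   rule's own level) plus cascade columns `n_records`, `n_lactations`,
#'   `n_cows`.
#' @export
apply_qc <- function(records, lactations, cows, alps, config = qc_config()) {
  cfg <- config
  records <- as.data.frame(records)
  lactations <- as.data.frame(lactations)
  cows <- as.data.frame(cows)
  alps <- as.data.frame(alps)

  ## referential integrity
  bad <- setdiff(records$lactation_id, lactations$lactation_id)
  if (length(bad)) {
    stop(sprintf("data-integrity error: record references unknown lactation_id '%s'",
                 bad[1]), call. = FALSE)
  }
  bad <- setdiff(lactations$cow_id, cows$cow_id)
  if (length(bad)) {
    stop(sprintf("data-integrity error: lactation references unknown cow_id '%s'",
                 bad[1]), call. = FALSE)
  }
  bad <- setdiff(stats::na.omit(lactations$alp_id), alps$alp_id)
  if (length(bad)) {
    stop(sprintf("data-integrity error: lactation references unknown alp_id '%s'",
                 bad[1]), call. = FALSE)
  }

  rep_tab <- .qc_rules
  rep_tab$n_removed <- 0L
  rep_tab$n_records <- 0L
  rep_tab$n_lactations <- 0L
  rep_tab$n_cows <- 0L

  tally <- function(rule, n_rec = 0L, n_lact = 0L, n_cow = 0L) {
    i <- match(rule, rep_tab$rule_id)
    rep_tab$n_records[i] <<- rep_tab$n_records[i] + n_rec
    rep_tab$n_lactations[i] <<- rep_tab$n_lactations[i] + n_lact
    rep_tab$n_cows[i] <<- rep_tab$n_cows[i] + n_cow
    rep_tab$n_removed[i] <<- switch(rep_tab$level[i],
                                    record = rep_tab$n_records[i],
                                    lactation = rep_tab$n_lactations[i],
                                    cow = rep_tab$n_cows[i])
  }
  drop_records <- function(idx, rule) {
    if (!length(idx)) return()
    tally(rule, n_rec = length(idx))
    records <<- records[-idx, , drop = FALSE]
  }
  drop_lactations <- function(ids, rule) {
    if (!length(ids)) return()
    ridx <- which(records$lactation_id %in% ids)
    tally(rule, n_rec = length(ridx), n_lact = length(ids))
    if (length(ridx)) records <<- records[-ridx, , drop = FALSE]
    lactations <<- lactations[!lactations$lactation_id %in% ids, , drop = FALSE]
  }
  drop_cows <- function(ids, rule) {
    if (!length(ids)) return()
    lids <- lactations$lactation_id[lactations$cow_id %in% ids]
    ridx <- which(records$lactation_id %in% lids)
    tally(rule, n_rec = length(ridx), n_lact = length(lids), n_cow = length(ids))
    if (length(ridx)) records <<- records[-ridx, , drop = FALSE]
    lactations <<- lactations[!lactations$lactation_id %in% lids, , drop = FALSE]
    cows <<- cows[!cows$cow_id %in% ids, , drop = FALSE]
  }

  ## (i) incomplete boundary years: trim records to the complete-year window
  drop_records(which(records$record_date < cfg$date_range[1] |
                     records$record_date > cfg$date_range[2]), "i")

  ## DIM per record (fixed from here on: dates no longer change)
  records$dim_ <- .dim_of(records$record_date,
                          lactations$calving_date[match(records$lactation_id,
                                                        lactations$lactation_id)])

  ## (ii) mean first-to-last insemination interval over the first lactations
  iv_mean <- vapply(split(lactations, lactations$cow_id), function(ll) {
    ll <- ll[order(ll$parity), , drop = FALSE]
    ll <- head(ll, cfg$n_insemination_lactations)
    spans <- vapply(ll$insemination_dates, function(s) {
      d <- .insem_dates(s)
      if (!length(d)) NA_real_ else as.numeric(max(d) - min(d))
    }, numeric(1))
    if (all(is.na(spans))) NA_real_ else mean(spans, na.rm = TRUE)
  }, numeric(1))
  drop_cows(names(iv_mean)[!is.na(iv_mean) &
                           iv_mean > cfg$max_insemination_interval], "ii")

  ## (iii) age at first calving: evaluated on the parity-1 lactation
  first <- lactations[lactations$parity == 1L, , drop = FALSE]
  birth <- cows$birth_date[match(first$cow_id, cows$cow_id)]
  age_days <- as.numeric(first$calving_date - birth)
  lo <- cfg$first_calving_age_years[1] * 365.25
  hi <- cfg$first_calving_age_years[2] * 365.25
  drop_cows(unique(first$cow_id[!is.na(age_days) &
                                (age_days < lo | age_days > hi)]), "iii")

  ## (iv) cow breed, (v) parental breeds
  drop_cows(cows$cow_id[!is.na(cows$breed) & !cows$breed %in% cfg$breeds], "iv")
  drop_cows(cows$cow_id[(!is.na(cows$sire_breed) & !cows$sire_breed %in% cfg$breeds) |
                        (!is.na(cows$dam_breed) & !cows$dam_breed %in% cfg$breeds)], "v")

  ## span-based lactation rules use the records surviving the record-level
  ## windows (rules xiii/xiv), so the cascade is idempotent
  span <- .span_records(records, cfg)
  span_max <- tapply(span$dim_, span$lactation_id, max)
  span_min <- tapply(span$dim_, span$lactation_id, min)

  ## (vi) lactation length
  short <- names(span_max)[span_max < cfg$min_lactation_days]
  drop_lactations(intersect(short, lactations$lactation_id), "vi")

  ## (vii) calving interval
  ci <- as.numeric(lactations$next_calving_date - lactations$calving_date)
  drop_lactations(lactations$lactation_id[!is.na(ci) &
                                          ci < cfg$min_calving_interval], "vii")

  ## (viii) alp altitude band
  alt <- alps$altitude_m[match(lactations$alp_id, alps$alp_id)]
  drop_lactations(lactations$lactation_id[!is.na(alt) &
    (alt < cfg$alp_altitude_range[1] | alt > cfg$alp_altitude_range[2])], "viii")

  ## (ix) excluded calving months
  cm <- as.integer(format(lactations$calving_date, "%m"))
  drop_lactations(lactations$lactation_id[cm %in% cfg$excluded_calving_months], "ix")

  ## (x) parity cap
  drop_lactations(lactations$lactation_id[lactations$parity > cfg$max_parity], "x")

  ## (xi) first record too late
  late <- names(span_min)[span_min > cfg$max_first_record_dim]
  drop_lactations(intersect(late, lactations$lactation_id), "xi")

  ## (xii) records before calving
  pre <- unique(records$lactation_id[records$dim_ < 0])
  drop_lactations(pre, "xii")

  ## (xiii) record DIM window
  drop_records(which(records$dim_ < cfg$dim_range[1] |
                     records$dim_ > cfg$dim_range[2]), "xiii")

  ## (xiv) second alping season: drop the later run's records only
  drop_records(.second_alp_run_idx(records), "xiv")

  records$dim_ <- NULL
  rownames(records) <- NULL
  rownames(lactations) <- NULL
  rownames(cows) <- NULL
  list(records = records, lactations = lactations, cows = cows, alps = alps,
       report = rep_tab)
}

#' Check removal-count conservation of a QC run
#'
#' Verifies that, at each level, the input size equals the surviving size
#' plus the total removals attributed across rules.
#'
#' @param before list with the input `records`, `lactations`, `cows`.
#' @param after the value of [apply_qc()].
#' @return `TRUE` (invisibly) if conservation holds, otherwise an error.
#' @export
check_qc_conservation <- function(before, after) {
  chk <- function(n_in, n_out, removed, what) {
    if (n_in != n_out + removed) {
      stop(sprintf("conservation violated at %s level: %d != %d + %d",
                   what, n_in, n_out, removed), call. = FALSE)
    }
  }
  chk(nrow(before$records), nrow(after$records), sum(after$report$n_records), "record")
  chk(nrow(before$lactations), nrow(after$lactations),
      sum(after$report$n_lactations), "lactation")
  chk(nrow(before$cows), nrow(after$cows), sum(after$report$n_cows), "cow")
  invisible(TRUE)
}

#' Write a QC filter report to CSV
#' @param report the `report` element of an [apply_qc()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report[, c("rule_id", "level", "n_removed")], path,
                   row.names = FALSE)
  invisible(path)
}
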