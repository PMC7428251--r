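## End-to-end orchestration: simulate (or read) -> QC -> exposure -> curves
## -> fits -> contrasts, with every threshold logged and deterministic
## outputs under a fixed seed.

#' Pipeline configuration
#'
#' Bundles every stage's settings. All analysis defaults are the
#' conventional ones: `k = 0.1`/day, squared IDW within 50 km, a lapse
#' gradient of -0.45 deg C/100 m, the 15 May--31 Aug alping window, alp
#' altitudes 1100--2600 m, tertile grouping, and a x100 pre-alping weight
#' multiplier for the per-month d-parameter fits.
#'
#' @param sim a [sim_config()] describing the synthetic herd, or `NULL` to
#'   read an existing herd from `input_dir` (written by [write_herd()]).
#' @param input_dir herd directory when `sim` is `NULL`.
#' @param months calving months to analyse (default September and February,
#'   representative of autumn and winter calving).
#' @param factors named list of [factor_spec()]s to contrast (default:
#'   altitude, parity, pregnancy stage at alp ascent, height, foot angle;
#'   THI/CSI are added when climate data are present).
#' @param k fixed decay constant.
#' @param qc a [qc_config()].
#' @param alping_window calendar window `c("mm-dd", "mm-dd")`.
#' @param exposure_window 3 or 30 days.
#' @param idw_power,idw_max_dist,lapse_gradient climate settings.
#' @param pre_alping_multiplier weight multiplier for the monthly fits.
#' @param bonferroni_m family size; default `length(factors) * length(months)`.
#' @param month_fit_parity_1 restrict the per-month curve fits to first
#'   lactations (the convention for cross-month comparisons, where parity
#'   and calving month are confounded).
#' @param seed integer seed for the simulation stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            months = c(9, 2), factors = NULL,
                            k = 0.1, qc = qc_config(),
                            alping_window = c("05-15", "08-31"),
                            exposure_window = 3,
                            idw_power = 2, idw_max_dist = 50000,
                            lapse_gradient = -0.45,
                            pre_alping_multiplier = 100,
                            bonferroni_m = NULL,
                            month_fit_parity_1 = TRUE,
                            seed = NULL) {
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, input_dir = input_dir, months = months,
                 factors = factors, k = k, qc = qc,
                 alping_window = alping_window,
                 exposure_window = exposure_window,
                 idw_power = idw_power, idw_max_dist = idw_max_dist,
                 lapse_gradient = lapse_gradient,
                 pre_alping_multiplier = pre_alping_multiplier,
                 bonferroni_m = bonferroni_m,
                 month_fit_parity_1 = month_fit_parity_1),
            class = "pipeline_config")
}

#' Built-in factor definitions
#'
#' The standard factor set: alp altitude (environmental, lactation-level),
#' parity as an explicit first-vs-third-or-higher contrast and pregnancy
#' stage at alp ascent (physiological), height at withers and foot angle
#' (morphological), plus record-level THI and CSI (environmental,
#' middle-vs-top tertiles) that require an `exposure` table in the dataset.
#'
#' @return a named list of [factor_spec()]s.
#' @export
default_factors <- function() {
  list(
    altitude = factor_spec("altitude", "environmental", function(ds) {
      ds$alps$altitude_m[match(ds$lactations$alp_id, ds$alps$alp_id)]
    }),
    lactation_number = factor_spec("lactation_number", "physiological", function(ds) {
      ifelse(ds$lactations$parity == 1, "lact1",
             ifelse(ds$lactations$parity >= 3, "lact3plus", NA_character_))
    }, grouping = "explicit"),
    pregnancy_stage = factor_spec("pregnancy_stage", "physiological", function(ds) {
      .pregnancy_stage_at_ascent(ds$lactations)
    }),
    height = factor_spec("height", "morphological", function(ds) {
      ds$cows$height_cm[match(ds$lactations$cow_id, ds$cows$cow_id)]
    }),
    foot_angle = factor_spec("foot_angle", "morphological", function(ds) {
      ds$cows$foot_angle[match(ds$lactations$cow_id, ds$cows$cow_id)]
    }),
    thi = factor_spec("thi_3d", "environmental", function(ds) {
      .exposure_by_record(ds, "thi")
    }, grouping = "t2_vs_t3", level = "record"),
    csi = factor_spec("csi_3d", "environmental", function(ds) {
      .exposure_by_record(ds, "csi")
    }, grouping = "t2_vs_t3", level = "record")
  )
}

# days pregnant at the alp-ascent date; conception called as the
# insemination preceding next_calving_date by 270-290 days when available,
# otherwise the last insemination.
.pregnancy_stage_at_ascent <- function(lactations) {
  vapply(seq_len(nrow(lactations)), function(i) {
    ins <- .insem_dates(lactations$insemination_dates[i])
    if (!length(ins)) return(NA_real_)
    conc <- NA
    nc <- lactations$next_calving_date[i]
    if (!is.na(nc)) {
      gest <- as.numeric(nc - ins)
      hit <- which(gest >= 270 & gest <= 290)
      if (length(hit)) conc <- ins[hit[length(hit)]]
    }
    if (is.na(conc)) conc <- max(ins)
    cal <- lactations$calving_date[i]
    yr <- as.integer(format(cal, "%Y"))
    asc <- as.Date(sprintf("%d-05-15", yr))
    if (asc <= cal) asc <- as.Date(sprintf("%d-05-15", yr + 1L))
    as.numeric(asc - conc)
  }, numeric(1))
}

# map an exposure table onto records (NA where missing or lowland)
.exposure_by_record <- function(ds, col) {
  if (is.null(ds$exposure)) {
    stop("dataset has no exposure table; run compute_exposure() first",
         call. = FALSE)
  }
  key_r <- paste(ds$records$lactation_id, ds$records$record_date)
  key_e <- paste(ds$exposure$lactation_id, ds$exposure$record_date)
  ds$exposure[[col]][match(key_r, key_e)]
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> quality control -> climate exposure (when climate
#' data are present) -> per-month averaged curves and model fits ->
#' factor contrasts. All outputs are written under `out_dir` as CSV/JSON,
#' plus `run.log` recording every threshold used. Deterministic for a fixed
#' `sim` seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the filtered dataset, `report`, `curves`,
#'   `fits` and `contrasts`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("alprun")) {
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("alpcurve pipeline run, %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  ## stage 1: data
  if (!is.null(cfg$sim)) {
    logf("simulate: n_cows=%d seed=%d", cfg$sim$n_cows, cfg$sim$seed)
    sim <- simulate_herd(cfg$sim)
  } else {
    logf("read herd from %s", cfg$input_dir)
    sim <- read_herd(cfg$input_dir)
    sim$climate <- NULL
  }

  ## stage 2: QC
  logf("qc: dim window [%d, %d], lactation >= %d d, altitude [%d, %d] m, parity <= %d",
       cfg$qc$dim_range[1], cfg$qc$dim_range[2], cfg$qc$min_lactation_days,
       cfg$qc$alp_altitude_range[1], cfg$qc$alp_altitude_range[2], cfg$qc$max_parity)
  qc <- apply_qc(sim$records, sim$lactations, sim$cows, sim$alps, cfg$qc)
  write_filter_report(qc$report, file.path(out_dir, "filter_report.csv"))
  write_herd(qc, file.path(out_dir, "filtered"))

  dataset <- list(records = qc$records, lactations = qc$lactations,
                  cows = qc$cows, alps = qc$alps)

  ## stage 3: exposure
  if (!is.null(sim$climate)) {
    logf("exposure: window=%d d, idw power=%g max_dist=%g m, lapse=%g degC/100m",
         cfg$exposure_window, cfg$idw_power, cfg$idw_max_dist, cfg$lapse_gradient)
    dataset$exposure <- compute_exposure(dataset$records, dataset$lactations,
                                         dataset$alps, sim$climate,
                                         window_days = cfg$exposure_window,
                                         gradient = cfg$lapse_gradient,
                                         power = cfg$idw_power,
                                         max_dist = cfg$idw_max_dist)
    utils::write.csv(dataset$exposure, file.path(out_dir, "exposure.csv"),
                     row.names = FALSE)
  }

  ## stage 4: per-month curves and fits
  logf("model: k=%g, alping window %s..%s, pre-alping weight x%g, parity-1 month fits: %s",
       cfg$k, cfg$alping_window[1], cfg$alping_window[2],
       cfg$pre_alping_multiplier, cfg$month_fit_parity_1)
  fit_lact <- dataset$lactations
  fit_rec <- dataset$records
  if (cfg$month_fit_parity_1) {
    fit_lact <- fit_lact[fit_lact$parity == 1L, , drop = FALSE]
    fit_rec <- fit_rec[fit_rec$lactation_id %in% fit_lact$lactation_id, , drop = FALSE]
  }
  curves <- list(); fits <- list()
  for (m in cfg$months) {
    mn <- month.abb[.month_num(m)]
    cv <- build_curve(fit_rec, fit_lact, m, alping_window = cfg$alping_window)
    cvw <- reweight_pre_alping(cv, cfg$pre_alping_multiplier)
    ft <- fit_lactation(cvw, "alping_full", k = cfg$k, refine = TRUE)
    curves[[mn]] <- cv
    fits[[mn]] <- ft
    write_curve(cv, file.path(out_dir, sprintf("curve_%s.csv", mn)))
    rep <- list(variant = ft$variant, k = ft$k, t1 = ft$t1, t2 = ft$t2,
                params = as.list(ft$params),
                se = as.list(sqrt(diag(ft$covariance))),
                loglik = ft$loglik, n_points = ft$n_points)
    jsonlite::write_json(rep, file.path(out_dir, sprintf("fit_%s.json", mn)),
                         auto_unbox = TRUE, digits = NA)
  }

  ## stage 5: contrasts
  factors <- cfg$factors
  if (is.null(factors)) {
    factors <- default_factors()
    if (is.null(dataset$exposure)) factors$thi <- factors$csi <- NULL
  }
  m_family <- if (is.null(cfg$bonferroni_m)) {
    length(factors) * length(cfg$months)
  } else cfg$bonferroni_m
  logf("contrasts: %d factors x %d months, Bonferroni m=%d",
       length(factors), length(cfg$months), m_family)
  contrasts <- list()
  for (m in cfg$months) {
    for (fn in names(factors)) {
      key <- paste0(fn, "_", month.abb[.month_num(m)])
      res <- tryCatch(
        contrast_factor(factors[[fn]], dataset, m, k = cfg$k,
                        alping_window = cfg$alping_window, m = m_family),
        alpcurve_contrast_infeasible = function(e) {
          logf("contrast %s infeasible: %s", key, conditionMessage(e))
          NULL
        })
      if (!is.null(res)) contrasts[[key]] <- res
    }
  }
  if (length(contrasts)) {
    utils::write.csv(contrast_table(contrasts),
                     file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  }
  logf("done: %d curves, %d contrasts", length(curves), length(contrasts))
  invisible(list(dataset = dataset, report = qc$report, curves = curves,
                 fits = fits, contrasts = contrasts, out_dir = out_dir))
}
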