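## Planting controlled QC violations on top of a clean synthetic herd.
## Each planted entity violates exactly one rule, so apply_qc()'s per-rule
## removal counts can be checked against the plant request.

# one clean lactation skeleton used as the template for plants
.plant_base <- function(tag, calving, alp_id, n_alp_runs = 0) {
  dims <- c(20, seq(50, 470, by = 30))
  list(
    cow = data.frame(cow_id = paste0("VC", tag), breed = "Braunvieh",
                     sire_breed = "Braunvieh", dam_breed = "Braunvieh",
                     birth_date = calving - round(2.8 * 365.25),
                     height_cm = 140, foot_angle = 5L, stringsAsFactors = FALSE),
    lact = data.frame(lactation_id = paste0("VL", tag), cow_id = paste0("VC", tag),
                      parity = 1L, calving_date = calving,
                      insemination_dates = format(calving + 80, "%Y-%m-%d"),
                      alp_id = alp_id, next_calving_date = calving + 80 + 283,
                      stringsAsFactors = FALSE),
    dims = dims
  )
}

.plant_records <- function(base, dims, site = "lowland", alp_id = NA_character_) {
  data.frame(cow_id = base$cow$cow_id, lactation_id = base$lact$lactation_id,
             record_date = base$lact$calving_date + dims,
             milk_kg = pmax(0.5, 20 - 0.02 * dims),
             fat_pct = 4, protein_pct = 3.4, scc = 80,
             site = site,
             alp_id = ifelse(site == "alp", alp_id, NA_character_),
             stringsAsFactors = FALSE)
}

#' Simulate a herd with planted quality-control violations
#'
#' Starts from a clean [simulate_herd()] dataset (which the QC cascade
#' leaves untouched) and adds, for each requested rule, entities that
#' violate exactly that rule and nothing else. The expected per-rule removal
#' counts are returned alongside, so `apply_qc()` accounting can be checked
#' against ground truth.
#'
#' @param config a [sim_config()] for the clean base herd.
#' @param plant named integer vector: rule id (`"i"` .. `"xiv"`) -> number
#'   of violating entities (records for record-level rules, lactations or
#'   cows otherwise).
#' @return a list with the herd tables and `expected`, a data.frame of
#'   `rule_id` and planted `n`.
#' @export
simulate_violations <- function(config = sim_config(n_cows = 50),
                                plant = integer(0)) {
  base <- simulate_herd(config)
  records <- base$records; lactations <- base$lactations
  cows <- base$cows; alps <- base$alps
  rules <- names(plant)
  bad <- setdiff(rules, .qc_rules$rule_id)
  if (length(bad)) stop("unknown rule id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  alp_ok <- alps$alp_id[1]
  tagn <- 0L
  add <- function(b, rec) {
    cows <<- rbind(cows, b$cow)
    lactations <<- rbind(lactations, b$lact)
    records <<- rbind(records, rec)
  }
  for (rule in rules) {
    for (rep_i in seq_len(plant[[rule]])) {
      tagn <- tagn + 1L
      tag <- sprintf("%03d", tagn)
      cal <- as.Date("2006-09-15")
      b <- .plant_base(tag, cal, alp_ok)
      rec <- .plant_records(b, b$dims)
      switch(rule,
        i = {  # one record beyond the complete-year window
          b <- .plant_base(tag, as.Date("2014-09-15"), alp_ok)
          rec <- .plant_records(b, c(20, seq(50, 260, by = 30), 285))  # <= 2015-06-27
          extra <- .plant_records(b, 300)                # 2015-07-12: trimmed
          add(b, rbind(rec, extra))
        },
        ii = {  # inseminations 120 days apart
          b$lact$insemination_dates <- paste(format(cal + c(60, 180), "%Y-%m-%d"),
                                             collapse = ";")
          b$lact$next_calving_date <- cal + 180 + 283
          add(b, rec)
        },
        iii = {  # first calf at 1.8 years
          b$cow$birth_date <- cal - round(1.8 * 365.25)
          add(b, rec)
        },
        iv = { b$cow$breed <- "Holstein"; add(b, rec) },
        v = { b$cow$sire_breed <- "Holstein"; add(b, rec) },
        vi = {  # records end at DIM 260
          rec <- .plant_records(b, c(20, seq(50, 260, by = 30)))
          add(b, rec)
        },
        vii = {  # next calving 280 days after this one
          b$lact$insemination_dates <- format(cal + 10, "%Y-%m-%d")
          b$lact$next_calving_date <- cal + 280
          rec <- .plant_records(b, c(20, seq(50, 260, by = 30), 275))
          add(b, rec)
        },
        viii = {  # alp below 1100 m
          low_id <- sprintf("ALOW%s", tag)
          alps <- rbind(alps, data.frame(alp_id = low_id, easting = 2650000,
                                          northing = 1150000, altitude_m = 950,
                                          region = alps$region[1],
                                          stringsAsFactors = FALSE))
          b$lact$alp_id <- low_id
          add(b, rec)
        },
        ix = {  # calving in May
          b <- .plant_base(tag, as.Date("2006-05-10"), alp_ok)
          add(b, .plant_records(b, b$dims))
        },
        x = { b$lact$parity <- 10L; add(b, rec) },
        xi = {  # first record at DIM 50
          rec <- .plant_records(b, seq(50, 470, by = 30))
          add(b, rec)
        },
        xii = {  # one record 10 days before calving
          rec <- rbind(.plant_records(b, -10), rec)
          add(b, rec)
        },
        xiii = {  # one record beyond DIM 500
          rec <- rbind(rec, .plant_records(b, 502))
          add(b, rec)
        },
        xiv = {  # a second alping run late in lactation
          dims <- b$dims
          first_run <- dims >= 245 & dims <= 350
          second_run <- dims >= 410
          site <- ifelse(first_run | second_run, "alp", "lowland")
          rec <- .plant_records(b, dims, site = site, alp_id = alp_ok)
          add(b, rec)
        })
    }
  }
  expected <- data.frame(rule_id = .qc_rules$rule_id,
                         n = vapply(.qc_rules$rule_id, function(r) {
                           n <- plant[r]
                           if (is.na(n)) 0L else as.integer(n)
                         }, integer(1)))
  ## record-level plants count removed records, not lactations
  expected$n[expected$rule_id == "xiv"] <-
    expected$n[expected$rule_id == "xiv"] * sum(.plant_base("x", as.Date("2006-09-15"),
                                                            "A")$dims >= 410)
  rownames(records) <- rownames(lactations) <- rownames(cows) <- NULL
  list(records = records, lactations = lactations, cows = cows, alps = alps,
       expected = expected)
}
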