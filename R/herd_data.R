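## Herd data model: cows, lactations, test-day records, alps.
##
## All tables are plain data.frames with fixed column sets; readers validate
## types row-by-row so malformed files fail with the offending row number.
## Insemination dates are stored as a single ";"-separated ISO-8601 string so
## the tables stay rectangular and CSV round-trips are exact.

.records_cols <- c("cow_id", "lactation_id", "record_date", "milk_kg",
                   "fat_pct", "protein_pct", "scc", "site", "alp_id")
.lactations_cols <- c("lactation_id", "cow_id", "parity", "calving_date",
                      "insemination_dates", "alp_id", "next_calving_date")
.cows_cols <- c("cow_id", "breed", "sire_breed", "dam_breed", "birth_date",
                "height_cm", "foot_angle")
.alps_cols <- c("alp_id", "easting", "northing", "altitude_m", "region")

.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error: %s is missing column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[cols]
}

.parse_dates <- function(x, col, what, required = FALSE) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  d <- as.Date(rep(NA_character_, length(x)))
  d[!blank] <- as.Date(x[!blank], format = "%Y-%m-%d")
  bad <- which(!blank & is.na(d))
  if (length(bad)) {
    stop(sprintf("parse error in %s, row %d: unparseable date '%s' in column '%s'",
                 what, bad[1], x[bad[1]], col), call. = FALSE)
  }
  if (required && any(blank)) {
    stop(sprintf("parse error in %s, row %d: missing date in column '%s'",
                 what, which(blank)[1], col), call. = FALSE)
  }
  d
}

.parse_num <- function(x, col, what, min = NULL) {
  xc <- as.character(x)
  blank <- is.na(xc) | !nzchar(trimws(xc))
  v <- suppressWarnings(as.numeric(xc))
  bad <- which(!blank & is.na(v))
  if (length(bad)) {
    stop(sprintf("parse error in %s, row %d: non-numeric value '%s' in column '%s'",
                 what, bad[1], xc[bad[1]], col), call. = FALSE)
  }
  if (!is.null(min)) {
    low <- which(!is.na(v) & v < min)
    if (length(low)) {
      stop(sprintf("parse error in %s, row %d: %s = %s is below %s",
                   what, low[1], col, format(v[low[1]]), format(min)),
           call. = FALSE)
    }
  }
  v
}

#' Read test-day milk records from CSV
#'
#' Expected columns: `cow_id, lactation_id, record_date, milk_kg, fat_pct,
#' protein_pct, scc, site, alp_id`. Dates are ISO-8601; `site` is `"lowland"`
#' or `"alp"`. Malformed dates or negative yields raise a parse error naming
#' the row.
#'
#' @param path path to a CSV file.
#' @return a data.frame of test-day records.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- .check_cols(df, .records_cols, basename(path))
  what <- basename(path)
  df$record_date <- .parse_dates(df$record_date, "record_date", what, required = TRUE)
  df$milk_kg <- .parse_num(df$milk_kg, "milk_kg", what, min = 0)
  df$fat_pct <- .parse_num(df$fat_pct, "fat_pct", what)
  df$protein_pct <- .parse_num(df$protein_pct, "protein_pct", what)
  df$scc <- .parse_num(df$scc, "scc", what)
  bad_site <- which(!df$site %in% c("lowland", "alp"))
  if (length(bad_site)) {
    stop(sprintf("parse error in %s, row %d: site must be 'lowland' or 'alp', got '%s'",
                 what, bad_site[1], df$site[bad_site[1]]), call. = FALSE)
  }
  df$alp_id[!nzchar(trimws(df$alp_id))] <- NA_character_
  df
}

#' Read lactation metadata from CSV
#'
#' Expected columns: `lactation_id, cow_id, parity, calving_date,
#' insemination_dates, alp_id, next_calving_date`; `insemination_dates` is a
#' `;`-separated list of ISO dates (possibly empty).
#'
#' @param path path to a CSV file.
#' @return a data.frame of lactations.
#' @export
read_lactations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- .check_cols(df, .lactations_cols, basename(path))
  what <- basename(path)
  df$parity <- as.integer(.parse_num(df$parity, "parity", what, min = 1))
  df$calving_date <- .parse_dates(df$calving_date, "calving_date", what, required = TRUE)
  df$next_calving_date <- .parse_dates(df$next_calving_date, "next_calving_date", what)
  df$alp_id[!nzchar(trimws(df$alp_id))] <- NA_character_
  df$insemination_dates[is.na(df$insemination_dates)] <- ""
  for (i in which(nzchar(df$insemination_dates))) {
    .parse_dates(strsplit(df$insemination_dates[i], ";", fixed = TRUE)[[1]],
                 "insemination_dates", what, required = TRUE)
  }
  df
}

#' Read cow metadata from CSV
#' @param path path to a CSV file with columns `cow_id, breed, sire_breed,
#'   dam_breed, birth_date, height_cm, foot_angle`.
#' @return a data.frame of cows.
#' @export
read_cows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- .check_cols(df, .cows_cols, basename(path))
  what <- basename(path)
  df$birth_date <- .parse_dates(df$birth_date, "birth_date", what)
  df$height_cm <- .parse_num(df$height_cm, "height_cm", what)
  df$foot_angle <- as.integer(.parse_num(df$foot_angle, "foot_angle", what))
  bad <- which(!is.na(df$foot_angle) & !(df$foot_angle %in% 1:9))
  if (length(bad)) {
    stop(sprintf("parse error in %s, row %d: foot_angle must be a score in 1..9",
                 what, bad[1]), call. = FALSE)
  }
  bad_h <- which(!is.na(df$height_cm) & df$height_cm <= 0)
  if (length(bad_h)) {
    stop(sprintf("parse error in %s, row %d: height_cm must be > 0",
                 what, bad_h[1]), call. = FALSE)
  }
  df
}

#' Read alp registry from CSV
#' @param path path to a CSV file with columns `alp_id, easting, northing,
#'   altitude_m, region` (planar coordinates and altitude in metres).
#' @return a data.frame of alps.
#' @export
read_alps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df <- .check_cols(df, .alps_cols, basename(path))
  what <- basename(path)
  df$easting <- .parse_num(df$easting, "easting", what)
  df$northing <- .parse_num(df$northing, "northing", what)
  df$altitude_m <- .parse_num(df$altitude_m, "altitude_m", what)
  bad <- which(!is.na(df$altitude_m) & (df$altitude_m < 0 | df$altitude_m > 4500))
  if (length(bad)) {
    stop(sprintf("parse error in %s, row %d: altitude_m %.0f outside plausible range [0, 4500]",
                 what, bad[1], df$altitude_m[bad[1]]), call. = FALSE)
  }
  df
}

#' Write a herd dataset to CSV files
#'
#' Writes `records.csv`, `lactations.csv`, `cows.csv` and `alps.csv` into
#' `dir`. The write/read round trip through [read_records()] and friends is
#' the identity on all fields.
#'
#' @param dataset a list with elements `records`, `lactations`, `cows`, `alps`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_herd <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, cols, file) {
    df <- as.data.frame(df)[cols]
    for (cl in names(df)) if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, na = "")
  }
  wr(dataset$records, .records_cols, "records.csv")
  wr(dataset$lactations, .lactations_cols, "lactations.csv")
  wr(dataset$cows, .cows_cols, "cows.csv")
  wr(dataset$alps, .alps_cols, "alps.csv")
  invisible(dir)
}

#' Read a herd dataset written by [write_herd()]
#' @param dir directory containing `records.csv`, `lactations.csv`,
#'   `cows.csv`, `alps.csv`.
#' @return a list with elements `records`, `lactations`, `cows`, `alps`.
#' @export
read_herd <- function(dir) {
  list(records    = read_records(file.path(dir, "records.csv")),
       lactations = read_lactations(file.path(dir, "lactations.csv")),
       cows       = read_cows(file.path(dir, "cows.csv")),
       alps       = read_alps(file.path(dir, "alps.csv")))
}

# split a ";"-joined insemination string into Date vector
.insem_dates <- function(s) {
  if (is.na(s) || !nzchar(s)) return(as.Date(character(0)))
  as.Date(strsplit(s, ";", fixed = TRUE)[[1]])
}

# days in milk: whole days since calving (DIM 0 = calving day)
.dim_of <- function(record_date, calving_date) {
  as.integer(record_date - calving_date)
}
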