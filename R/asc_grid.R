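## Minimal ESRI ASCII grid (.asc) I/O and nearest-cell sampling.
## Row 1 of the value matrix is the northernmost row, as in the file format.

#' Construct a climate grid
#'
#' @param variable one of `"t_max"`, `"t_mean"`, `"rain"` (or any label).
#' @param date the calendar date the grid is valid for.
#' @param xll,yll coordinates of the lower-left corner of the grid, in m.
#' @param cell_size cell edge length in m.
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param reference_elevation optional matrix of the same shape giving the
#'   elevation (m) each temperature value refers to; required for lapse
#'   correction of temperature variables.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(variable, date, xll, yll, cell_size, values,
                         reference_elevation = NULL) {
  values <- as.matrix(values)
  if (!is.null(reference_elevation)) {
    reference_elevation <- as.matrix(reference_elevation)
    if (!identical(base::dim(values), base::dim(reference_elevation))) {
      stop("values and reference_elevation must share their shape", call. = FALSE)
    }
  }
  structure(list(variable = variable, date = as.Date(date),
                 xll = xll, yll = yll, cell_size = cell_size,
                 values = values, reference_elevation = reference_elevation),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s @ %s: %d x %d cells of %g m, origin (%g, %g)\n",
              x$variable, format(x$date), nrow(x$values), ncol(x$values),
              x$cell_size, x$xll, x$yll))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @param variable,date metadata attached to the returned grid.
#' @return a `climate_grid` (without reference elevation; attach one via
#'   [climate_grid()] if lapse correction is needed).
#' @export
read_asc_grid <- function(path, variable = NA_character_, date = NA) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop(sprintf("ASCII grid %s: expected %d values, found %d", path,
                 hdr$ncols * hdr$nrows, length(vals)), call. = FALSE)
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  climate_grid(variable, date, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m)
}

#' Write a climate grid as an ESRI ASCII grid
#' @param grid a `climate_grid`.
#' @param path output path.
#' @param nodata value written for missing cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sample a grid at planar coordinates (nearest cell)
#'
#' @param grid a `climate_grid`.
#' @param easting,northing coordinate vectors in m.
#' @return a list with `value` and `elevation` vectors (`elevation` is `NA`
#'   when the grid carries no reference elevation); coordinates outside the
#'   grid yield `NA`.
#' @export
grid_sample <- function(grid, easting, northing) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((easting - grid$xll) / grid$cell_size) + 1
  row_from_bottom <- floor((northing - grid$yll) / grid$cell_size) + 1
  row <- nr - row_from_bottom + 1
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr &
    !is.na(col) & !is.na(row)
  val <- rep(NA_real_, length(easting))
  ele <- rep(NA_real_, length(easting))
  idx <- cbind(row[ok], col[ok])
  val[ok] <- grid$values[idx]
  if (!is.null(grid$reference_elevation)) ele[ok] <- grid$reference_elevation[idx]
  list(value = val, elevation = ele)
}
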