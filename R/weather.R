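#' Gridded daily weather cube
#'
#' Container for a daily Tmin/Tmax raster series: consecutive calendar
#' dates, one grid per day per variable, and a shared grid geometry.
#' Fahrenheit input is converted to Celsius (temperature *data* are
#' converted exactly; only thresholds in parameter files follow the
#' integer-Fahrenheit rounding convention). Element-wise `tmin > tmax`
#' violations are repaired by swapping, with a warning.
#'
#' @param dates Consecutive `Date` vector (one per day).
#' @param tmin,tmax 3-d arrays `[rows, cols, days]`, degrees C (or F, see
#'   `units`). Row 1 = north.
#' @param geo A [grid_geometry()].
#' @param units `"C"` (default) or `"F"`.
#' @return A `weather_cube` list with fields `dates`, `tmin`, `tmax`,
#'   `geo`, `nrow`, `ncol`, `ndays`.
#' @export
weather_cube <- function(dates, tmin, tmax, geo = grid_geometry(),
                         units = c("C", "F")) {
  units <- match.arg(units)
  dates <- as.Date(dates)
  if (length(dates) > 1L && any(diff(dates) != 1L)) {
    gaps <- dates[which(diff(dates) != 1L)]
    stop("weather dates must be consecutive; gap(s) after ",
         paste(utils::head(gaps, 5), collapse = ", "), call. = FALSE)
  }
  if (is.matrix(tmin)) tmin <- array(tmin, c(dim(tmin), 1L))
  if (is.matrix(tmax)) tmax <- array(tmax, c(dim(tmax), 1L))
  stopifnot(identical(dim(tmin), dim(tmax)),
            dim(tmin)[3L] == length(dates))
  if (units == "F") {
    tmin <- (tmin - 32) * 5 / 9
    tmax <- (tmax - 32) * 5 / 9
  }
  bad <- !is.na(tmin) & !is.na(tmax) & tmin > tmax
  if (any(bad)) {
    warning(sum(bad), " cell-day(s) with tmin > tmax; values swapped",
            call. = FALSE)
    tmp <- tmin[bad]
    tmin[bad] <- tmax[bad]
    tmax[bad] <- tmp
  }
  structure(list(dates = dates, tmin = tmin, tmax = tmax, geo = geo,
                 nrow = dim(tmin)[1L], ncol = dim(tmin)[2L],
                 ndays = dim(tmin)[3L]),
            class = "weather_cube")
}

#' @export
print.weather_cube <- function(x, ...) {
  cat("<weather_cube>", x$nrow, "x", x$ncol, "cells,", x$ndays, "days (",
      format(x$dates[1]), "to", format(x$dates[x$ndays]), ")\n")
  invisible(x)
}

#' Extract the daily weather series of one grid cell
#'
#' @param cube A [weather_cube()].
#' @param row,col Cell indices (row 1 = north).
#' @return Data frame with `date`, `tmin`, `tmax`, directly consumable by
#'   [run_cohort()].
#' @export
cube_cell_series <- function(cube, row, col) {
  stopifnot(inherits(cube, "weather_cube"))
  data.frame(date = cube$dates,
             tmin = cube$tmin[row, col, ],
             tmax = cube$tmax[row, col, ])
}

#' Crop a weather cube to a coordinate extent
#'
#' Keeps the cells whose centers fall inside the extent and updates the
#' grid geometry accordingly.
#'
#' @param cube A [weather_cube()].
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @return The cropped `weather_cube`.
#' @export
crop_cube <- function(cube, extent) {
  stopifnot(inherits(cube, "weather_cube"), length(extent) == 4L)
  g <- cube$geo
  xc <- g$xmin + (seq_len(cube$ncol) - 0.5) * g$xres
  yc <- g$ymax - (seq_len(cube$nrow) - 0.5) * g$yres
  cols <- which(xc >= extent[1L] & xc <= extent[2L])
  rows <- which(yc >= extent[3L] & yc <= extent[4L])
  if (!length(rows) || !length(cols))
    stop("crop extent contains no grid cells", call. = FALSE)
  geo <- grid_geometry(xmin = g$xmin + (min(cols) - 1L) * g$xres,
                       ymax = g$ymax - (min(rows) - 1L) * g$yres,
                       xres = g$xres, yres = g$yres, crs = g$crs)
  weather_cube(cube$dates,
               cube$tmin[rows, cols, , drop = FALSE],
               cube$tmax[rows, cols, , drop = FALSE],
               geo)
}

# subset a cube by row/col index ranges (used by the tiler)
.subset_cube <- function(cube, rows, cols) {
  g <- cube$geo
  geo <- grid_geometry(xmin = g$xmin + (min(cols) - 1L) * g$xres,
                       ymax = g$ymax - (min(rows) - 1L) * g$yres,
                       xres = g$xres, yres = g$yres, crs = g$crs)
  weather_cube(cube$dates,
               cube$tmin[rows, cols, , drop = FALSE],
               cube$tmax[rows, cols, , drop = FALSE],
               geo)
}

#' Write a weather cube as per-day GeoTIFF pairs
#'
#' Writes `tmin_YYYY-MM-DD.tif` / `tmax_YYYY-MM-DD.tif` single-band files
#' into a directory, the on-disk interchange format consumed by
#' [read_weather()].
#'
#' @param cube A [weather_cube()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_weather <- function(cube, dir) {
  stopifnot(inherits(cube, "weather_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(cube$ndays)) {
    d <- format(cube$dates[i])
    write_geotiff(cube$tmin[, , i], file.path(dir, paste0("tmin_", d, ".tif")),
                  cube$geo, band_names = d)
    write_geotiff(cube$tmax[, , i], file.path(dir, paste0("tmax_", d, ".tif")),
                  cube$geo, band_names = d)
  }
  invisible(dir)
}

#' Read daily Tmin/Tmax rasters into a weather cube
#'
#' Reads per-day GeoTIFF pairs named `tmin_YYYY-MM-DD.tif` /
#' `tmax_YYYY-MM-DD.tif` from a directory. The requested date range must
#' be fully covered: any gap is an error listing the missing dates.
#'
#' @param source Directory containing the per-day files.
#' @param extent Optional crop extent `c(xmin, xmax, ymin, ymax)`.
#' @param dates Optional `Date` vector (or length-2 range) restricting the
#'   days read; defaults to every date found.
#' @param units `"C"` or `"F"`; Fahrenheit values are converted.
#' @return A [weather_cube()].
#' @export
read_weather <- function(source, extent = NULL, dates = NULL,
                         units = c("C", "F")) {
  units <- match.arg(units)
  if (!dir.exists(source)) stop("weather source not found: ", source,
                                call. = FALSE)
  files <- list.files(source, pattern = "^tmin_\\d{4}-\\d{2}-\\d{2}\\.tif$")
  found <- as.Date(sub("^tmin_(.*)\\.tif$", "\\1", files))
  if (!length(found)) stop("no tmin_*.tif files in ", source, call. = FALSE)
  found <- sort(found)
  if (is.null(dates)) {
    dates <- seq(min(found), max(found), by = 1)
  } else if (length(dates) == 2L) {
    dates <- seq(as.Date(dates[1L]), as.Date(dates[2L]), by = 1)
  } else {
    dates <- as.Date(dates)
  }
  missing_tmin <- dates[!dates %in% found]
  fmax <- file.path(source, paste0("tmax_", format(dates), ".tif"))
  missing_tmax <- dates[!file.exists(fmax)]
  gaps <- sort(unique(c(missing_tmin, missing_tmax)))
  if (length(gaps))
    stop("missing weather for date(s): ",
         paste(format(utils::head(gaps, 10)), collapse = ", "),
         if (length(gaps) > 10) " ...", call. = FALSE)

  first <- read_geotiff(file.path(source, paste0("tmin_", format(dates[1L]),
                                                 ".tif")))
  nr <- dim(first$data)[1L]; nc <- dim(first$data)[2L]
  tmin <- array(NA_real_, c(nr, nc, length(dates)))
  tmax <- array(NA_real_, c(nr, nc, length(dates)))
  for (i in seq_along(dates)) {
    d <- format(dates[i])
    tmin[, , i] <- read_geotiff(file.path(source,
                                          paste0("tmin_", d, ".tif")))$data[, , 1L]
    tmax[, , i] <- read_geotiff(file.path(source,
                                          paste0("tmax_", d, ".tif")))$data[, , 1L]
  }
  cube <- weather_cube(dates, tmin, tmax, first$geo, units = units)
  if (!is.null(extent)) cube <- crop_cube(cube, extent)
  cube
}
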