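# Writing model outputs: multi-band GeoTIFF families (one band per
# sampled day), PNG summary maps, and a JSON run manifest.

#' Write the outputs of a gridded run to disk
#'
#' Writes one multi-band GeoTIFF per output family (bands named by the
#' sampled dates), end-of-run voltinism and event-day rasters with their
#' exclusion-masked variants, PNG summary maps (voltinism, combined
#' exclusion classes, and each configured event with month-day date
#' labels), and a `manifest.json` recording the configuration, species,
#' sentinel codes, and file list. Masked rasters use the sentinels
#' `-1` (moderate exclusion) and `-2` (severe exclusion); nodata is
#' `-9999`.
#'
#' @param run A `pheno_grid_run` from [run_grid()] or [tile_and_mosaic()].
#' @param dir Output directory (created if needed).
#' @param png Also render PNG summary maps?
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(run, dir, png = TRUE) {
  stopifnot(inherits(run, "pheno_grid_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geo <- run$geo
  bands <- format(run$sample_date)
  files <- character()
  wt <- function(data, name, datatype = "float32", bnames = bands) {
    path <- file.path(dir, paste0(name, ".tif"))
    write_geotiff(data, path, geo, band_names = bnames,
                  datatype = datatype)
    files <<- c(files, path)
  }

  wt(run$accum_dd, "accumdd")
  wt(run$stage_code, "stage_mid", "int32")
  wt(run$cold_accum, "coldstress")
  wt(run$heat_accum, "heatstress")
  wt(run$cold_class, "excl_cold", "int32")
  wt(run$heat_class, "excl_heat", "int32")
  wt(run$all_class, "excl_all", "int32")
  wt(run$voltinism, "voltinism", "int32", bnames = "final")
  lay <- dimnames(run$pop_frac)[[3L]]
  keep <- vapply(seq_along(lay),
                 function(j) any(run$pop_frac[, , j, ] > 0, na.rm = TRUE),
                 logical(1))
  for (j in which(keep))
    wt(run$pop_frac[, , j, ], paste0("popfrac_", lay[j]))
  for (e in names(run$events)) {
    wt(run$events[[e]]$earliest, paste0("event_", e, "_earliest"),
       "int32", bnames = "final")
    wt(run$events[[e]]$average, paste0("event_", e, "_avg"),
       "int32", bnames = "final")
  }
  suffix <- c(severe_only = "_exclsev", severe_and_moderate = "_exclall")
  for (m in names(run$masked)) {
    mk <- run$masked[[m]]
    wt(mk$stage_code, paste0("stage_mid", suffix[[m]]), "int32")
    wt(mk$voltinism, paste0("voltinism", suffix[[m]]), "int32",
       bnames = "final")
    for (e in names(mk$events)) {
      wt(mk$events[[e]]$earliest,
         paste0("event_", e, "_earliest", suffix[[m]]), "int32", "final")
      wt(mk$events[[e]]$average,
         paste0("event_", e, "_avg", suffix[[m]]), "int32", "final")
    }
  }

  if (png) {
    yr <- as.integer(format(run$dates[1L], "%Y"))
    files <- c(files, plot_voltinism_map(run, file.path(dir,
                                                        "map_voltinism.png")))
    files <- c(files, plot_exclusion_map(run, file.path(dir,
                                                        "map_excl_all.png")))
    for (e in names(run$events))
      files <- c(files, plot_event_map(
        run, e, file.path(dir, paste0("map_event_", e, ".png")), year = yr))
  }

  manifest <- list(
    package = "phenorisk",
    version = as.character(utils::packageVersion("phenorisk")),
    species = run$params$name,
    config = list(n_cohorts = run$config$n_cohorts,
                  sample_every = run$config$sample_every,
                  n_tiles = run$config$n_tiles,
                  seed = run$config$seed,
                  weighted_event_average = run$config$weighted,
                  events = run$config$events),
    cohorts = as.data.frame(run$cohorts),
    grid = list(nrow = dim(run$voltinism)[1L],
                ncol = dim(run$voltinism)[2L],
                xmin = geo$xmin, ymax = geo$ymax,
                xres = geo$xres, yres = geo$yres, crs = geo$crs),
    dates = list(start = format(run$dates[1L]),
                 end = format(run$dates[length(run$dates)]),
                 sampled = bands),
    codes = list(
      stage_code = "10 * generation + stage (ow=0 egg=1 larva=2 pupa=3 adult=4)",
      masked_moderate = -1, masked_severe = -2, nodata = -9999),
    files = basename(files)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(files, manifest_path))
}

#' Convert day-of-year to a month-day label
#'
#' @param doy Day of year (1-based).
#' @param year Calendar year (decides leap-day handling).
#' @return Character labels like `"Mar-01"`.
#' @export
doy_label <- function(doy, year = 2018L) {
  format(as.Date(paste0(year, "-01-01")) + (doy - 1), "%b-%d")
}

.grid_df <- function(m, geo) {
  nr <- nrow(m); nc <- ncol(m)
  data.frame(
    x = rep(geo$xmin + (seq_len(nc) - 0.5) * geo$xres, each = nr),
    y = rep(geo$ymax - (seq_len(nr) - 0.5) * geo$yres, times = nc),
    value = as.vector(m))
}

.excl_cols <- c(`excl.-moderate` = "grey65", `excl.-severe` = "grey35")

#' Render a voltinism summary map
#'
#' Continuous map of the number of generations, with cells under
#' moderate/severe exclusion (from the masked variant) drawn as
#' categorical grey classes.
#'
#' @param run A `pheno_grid_run`.
#' @param path PNG output path.
#' @param mode Masking mode used for the exclusion overlay.
#' @return `path`, invisibly.
#' @export
plot_voltinism_map <- function(run, path,
                               mode = "severe_and_moderate") {
  m <- run$masked[[mode]]$voltinism
  .render_masked_map(m, run$geo, path,
                     title = paste0("Voltinism - ", run$params$name),
                     legend = "generations", labeller = identity)
}

#' Render an event-day summary map with calendar-date labels
#'
#' @param run A `pheno_grid_run`.
#' @param event Event id, e.g. `"ow_g0"` (see `names(run$events)`).
#' @param path PNG output path.
#' @param which `"average"` or `"earliest"`.
#' @param mode Masking mode for the exclusion overlay.
#' @param year Calendar year for date labels.
#' @return `path`, invisibly.
#' @export
plot_event_map <- function(run, event, path, which = "average",
                           mode = "severe_and_moderate", year = 2018L) {
  m <- run$masked[[mode]]$events[[event]][[which]]
  .render_masked_map(m, run$geo, path,
                     title = paste0("Event ", event, " (", which, ") - ",
                                    run$params$name),
                     legend = "date",
                     labeller = function(b) doy_label(b, year))
}

#' Render the combined stress-exclusion class map
#'
#' @param run A `pheno_grid_run`.
#' @param path PNG output path.
#' @param day Index into the sampled days (default: last).
#' @return `path`, invisibly.
#' @export
plot_exclusion_map <- function(run, path,
                               day = length(run$sample_idx)) {
  df <- .grid_df(run$all_class[, , day], run$geo)
  df$class <- factor(names(exclusion_levels)[df$value + 1L],
                     levels = names(exclusion_levels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                        fill = class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(none = "palegreen3", .excl_cols), drop = FALSE,
      na.value = "white", name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Climate stress exclusion - ",
                                 run$params$name),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
  invisible(path)
}

.render_masked_map <- function(m, geo, path, title, legend, labeller) {
  df <- .grid_df(m, geo)
  df$class <- ifelse(is.na(df$value), NA,
                     ifelse(df$value == -2, "excl.-severe",
                            ifelse(df$value == -1, "excl.-moderate",
                                   "value")))
  dfv <- df[!is.na(df$class) & df$class == "value", ]
  dfm <- df[!is.na(df$class) & df$class != "value", ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = dfv,
                         ggplot2::aes(x = x, y = y,
                                      fill = value)) +
    ggplot2::scale_fill_viridis_c(name = legend, labels = labeller) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(dfm)) {
    p <- p +
      ggplot2::geom_raster(data = dfm,
                           ggplot2::aes(x = x, y = y,
                                        alpha = class),
                           fill = "grey45") +
      ggplot2::scale_alpha_manual(
        values = c(`excl.-moderate` = 0.55, `excl.-severe` = 1),
        name = "excluded")
  }
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
  invisible(path)
}

#' Export per-cell trajectories as CSV for point debugging
#'
#' Writes the sampled middle-cohort stage code, generation, accumulated
#' degree-days and stress accumulations of selected cells.
#'
#' @param run A `pheno_grid_run`.
#' @param cells Data frame with `row` and `col` columns.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_cell_csv <- function(run, cells, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$row[i]; cc <- cells$col[i]
    data.frame(row = r, col = cc,
               date = format(run$sample_date),
               day = run$sample_day,
               stage_code = run$stage_code[r, cc, ],
               accum_dd = run$accum_dd[r, cc, ],
               cold_accum = run$cold_accum[r, cc, ],
               heat_accum = run$heat_accum[r, cc, ],
               all_class = run$all_class[r, cc, ])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
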