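# Gridded orchestration: run the cohort engine over every cell of a
# weather cube, combine cohorts, classify stress exclusions, optionally
# tile large extents (bit-identical to the untiled run), and write
# multi-band GeoTIFFs, summary maps, and a JSON run manifest.

#' Run configuration
#'
#' Bundles the options of a gridded model run.
#'
#' @param n_cohorts Number of overwintering cohorts (>= 1).
#' @param sample_every Output sampling interval in days (1, 2, 7, 10, 14
#'   or 30); the final day is always included.
#' @param events Data frame with columns `stage` (one of `"ow"`, `"egg"`,
#'   `"larva"`, `"pupa"`, `"adult"`) and `generation` (0-based, below the
#'   species' `max_event_generations`) selecting the phenological event
#'   maps to produce. Default: overwintering emergence (generation 0).
#' @param weighted Weight average event dates by cohort fraction?
#' @param n_tiles Number of tiles to split the grid into (results are
#'   identical for any tiling).
#' @param seed Integer seed (only synthetic weather consumes randomness).
#' @return A `run_config` list.
#' @export
run_config <- function(n_cohorts = 7L,
                       sample_every = 30L,
                       events = data.frame(stage = "ow", generation = 0L),
                       weighted = TRUE,
                       n_tiles = 1L,
                       seed = 1L) {
  stopifnot(n_cohorts >= 1L, n_tiles >= 1L,
            all(c("stage", "generation") %in% names(events)),
            all(events$stage %in% .event_slots))
  structure(list(n_cohorts = as.integer(n_cohorts),
                 sample_every = .check_sample_every(sample_every),
                 events = events, weighted = isTRUE(weighted),
                 n_tiles = as.integer(n_tiles), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the phenology and climatic suitability model over a grid
#'
#' Steps through every day of the weather cube, advancing all cohorts in
#' every grid cell, accumulating cold and heat stress, and sampling
#' results every `config$sample_every` days. Stage/generation maps are
#' kept for the middle cohort; population composition uses all cohort
#' weights; event-day maps (earliest and cohort-averaged day of year) are
#' computed after the last day. Exclusion masks (severe only, and severe
#' plus moderate) are applied to every phenology output except
#' accumulated degree-days.
#'
#' @param cube A [weather_cube()].
#' @param params A [species_params()].
#' @param config A [run_config()].
#' @return A `pheno_grid_run` object; see Details for its fields.
#' @details Fields of the returned object (grids are row 1 = north):
#' * `accum_dd`: accumulated degree-days (first cohort, larval
#'   thresholds), one layer per sampled day; never masked.
#' * `stage_code`: middle-cohort stage + generation code per sampled day,
#'   `10 * generation + stage index` with overwintering = 0, egg = 1,
#'   larva = 2, pupa = 3, adult = 4 (generation capped at
#'   `max_event_generations`).
#' * `pop_frac`: fraction of the population per (generation, stage) layer
#'   and sampled day.
#' * `cold_accum`, `heat_accum`, `cold_class`, `heat_class`, `all_class`:
#'   stress accumulations and exclusion classes per sampled day.
#' * `voltinism`: middle-cohort generation count on the last day;
#'   `voltinism_by_cohort` keeps all cohorts.
#' * `events`: per configured event, `earliest` and `average` day-of-year
#'   grids.
#' * `masked`: the two exclusion-masked variants (`severe_only`,
#'   `severe_and_moderate`) of stage code, voltinism, and event grids,
#'   using each sampled day's exclusion state for per-day layers and the
#'   final day's for end-of-run maps.
#' @export
run_grid <- function(cube, params, config = run_config()) {
  stopifnot(inherits(cube, "weather_cube"),
            inherits(params, "species_params"),
            inherits(config, "run_config"))
  gmax <- params$max_event_generations
  if (any(config$events$generation < 0L |
          config$events$generation >= gmax))
    stop("configured event generations must be in [0, ",
         gmax - 1L, "]", call. = FALSE)

  nr <- cube$nrow; nc <- cube$ncol; n <- nr * nc
  ndays <- cube$ndays
  doy <- as.POSIXlt(cube$dates)$yday + 1L
  samp <- .sample_indices(ndays, config$sample_every)
  ns <- length(samp)

  cohorts <- make_cohorts(params, config$n_cohorts)
  ncoh <- nrow(cohorts)
  mid <- middle_cohort(cohorts)
  states <- lapply(seq_len(ncoh), function(i) .init_cells(n, params))

  # population composition layers: generations 0..gmax (gmax = "gmax+")
  gen_levels <- 0:gmax
  layer_names <- as.vector(outer(.event_slots, gen_levels,
                                 function(s, g) paste0("g", g, "_", s)))
  nlay <- length(layer_names)

  grids <- function(k = ns) array(NA_real_, c(nr, nc, k))
  out <- list(
    dates = cube$dates, sample_idx = samp, sample_day = doy[samp],
    sample_date = cube$dates[samp], geo = cube$geo,
    accum_dd = grids(), stage_code = grids(),
    pop_frac = array(0, c(nr, nc, nlay, ns),
                     dimnames = list(NULL, NULL, layer_names, NULL)),
    cold_accum = grids(), heat_accum = grids(),
    cold_class = grids(), heat_class = grids(), all_class = grids()
  )

  cold_acc <- numeric(n); heat_acc <- numeric(n)
  wx_missing <- integer(n)  # cell-days with no usable weather at all
  k <- 1L
  for (i in seq_len(ndays)) {
    tmin_v <- as.vector(cube$tmin[, , i])
    tmax_v <- as.vector(cube$tmax[, , i])
    wx_missing <- wx_missing + as.integer(is.na(tmin_v) & is.na(tmax_v))
    dd_mat <- daily_stage_dd(tmin_v, tmax_v, params)
    cs <- daily_cold_stress(tmin_v, params$coldstress_threshold)
    hs <- daily_heat_stress(tmax_v, params$heatstress_threshold)
    cold_acc <- cold_acc + ifelse(is.na(cs), 0, cs)
    heat_acc <- heat_acc + ifelse(is.na(hs), 0, hs)
    for (cix in seq_len(ncoh)) {
      states[[cix]] <- .step_cells(states[[cix]], dd_mat, params,
                                   cohorts$emergence_dd[cix], doy[i])
    }
    if (k <= ns && samp[k] == i) {
      st_mid <- states[[mid]]
      all_na <- wx_missing == i  # no weather seen yet for this cell
      out$accum_dd[, , k] <- .vec_grid(
        ifelse(all_na, NA_real_, states[[1L]]$cum_dd), nr, nc)
      code <- 10 * pmin(st_mid$generation, gmax) +
        ifelse(st_mid$in_ow, 0L, st_mid$stage)
      code[all_na] <- NA_real_
      out$stage_code[, , k] <- .vec_grid(code, nr, nc)
      for (cix in seq_len(ncoh)) {
        st <- states[[cix]]
        lay <- (pmin(st$generation, gmax)) * 5L +
          ifelse(st$in_ow, 1L, st$stage + 1L)
        for (u in unique(lay)) {
          sel <- lay == u
          out$pop_frac[, , u, k] <- out$pop_frac[, , u, k] +
            .vec_grid(as.numeric(sel) * cohorts$weight[cix], nr, nc)
        }
      }
      ca <- cold_acc; ha <- heat_acc
      ca[all_na] <- NA; ha[all_na] <- NA
      out$cold_accum[, , k] <- .vec_grid(ca, nr, nc)
      out$heat_accum[, , k] <- .vec_grid(ha, nr, nc)
      out$cold_class[, , k] <- .vec_grid(
        classify_exclusion(ca, params$coldstress_units_max1,
                           params$coldstress_units_max2), nr, nc)
      out$heat_class[, , k] <- .vec_grid(
        classify_exclusion(ha, params$heatstress_units_max1,
                           params$heatstress_units_max2), nr, nc)
      out$all_class[, , k] <- combine_exclusion(out$cold_class[, , k],
                                                out$heat_class[, , k])
      k <- k + 1L
    }
  }

  never_seen <- wx_missing == ndays
  volt_coh <- matrix(vapply(states, function(st) {
    g <- as.numeric(st$generation)
    g[never_seen] <- NA_real_
    g
  }, numeric(n)), nrow = n)
  out$voltinism_by_cohort <- array(volt_coh, c(nr, nc, ncoh))
  out$voltinism <- .vec_grid(volt_coh[, mid], nr, nc)
  out$missing_days <- .vec_grid(as.numeric(states[[1L]]$missing), nr, nc)

  # event-day maps: earliest and weighted-average day across cohorts
  out$events <- list()
  for (e in seq_len(nrow(config$events))) {
    s <- config$events$stage[e]
    g <- config$events$generation[e]
    slot <- match(s, .event_slots)
    days <- matrix(vapply(states,
                          function(st) as.numeric(st$event_day[, g + 1L, slot]),
                          numeric(n)), nrow = n)  # n x ncoh
    set <- !is.na(days)
    earliest <- suppressWarnings(apply(days, 1L, min, na.rm = TRUE))
    earliest[!is.finite(earliest)] <- NA_real_
    wmat <- matrix(cohorts$weight, n, ncoh, byrow = TRUE)
    if (!config$weighted) wmat[] <- 1
    wmat[!set] <- 0
    wsum <- rowSums(wmat)
    avg <- ifelse(wsum > 0,
                  round(rowSums(days * wmat, na.rm = TRUE) / wsum),
                  NA_real_)
    out$events[[paste0(s, "_g", g)]] <- list(
      earliest = .vec_grid(earliest, nr, nc),
      average = .vec_grid(avg, nr, nc))
  }

  # exclusion-masked variants of every phenology output (not accum_dd)
  final_cls <- out$all_class[, , ns]
  out$masked <- list()
  for (mode in c("severe_only", "severe_and_moderate")) {
    mk <- list()
    sc <- out$stage_code
    for (kk in seq_len(ns))
      sc[, , kk] <- apply_exclusion_mask(out$stage_code[, , kk],
                                         out$all_class[, , kk], mode)
    mk$stage_code <- sc
    mk$voltinism <- apply_exclusion_mask(out$voltinism, final_cls, mode)
    mk$events <- lapply(out$events, function(ev)
      list(earliest = apply_exclusion_mask(ev$earliest, final_cls, mode),
           average = apply_exclusion_mask(ev$average, final_cls, mode)))
    out$masked[[mode]] <- mk
  }

  out$params <- params
  out$config <- config
  out$cohorts <- cohorts
  structure(out, class = "pheno_grid_run")
}

.vec_grid <- function(v, nr, nc) {
  dim(v) <- c(nr, nc)
  v
}

#' @export
print.pheno_grid_run <- function(x, ...) {
  cat("<pheno_grid_run>", dim(x$voltinism)[1L], "x", dim(x$voltinism)[2L],
      "cells,", length(x$dates), "days,", nrow(x$cohorts), "cohorts\n")
  cat("voltinism (middle cohort):",
      paste(range(x$voltinism, na.rm = TRUE), collapse = "-"), "\n")
  invisible(x)
}

#' Run the grid model tile-wise and mosaic the results
#'
#' Splits the cube into `n_tiles` rectangular tiles, runs [run_grid()]
#' on each, and stitches the outputs back together. Because the model has
#' no spatial coupling between cells, the mosaic is bit-identical to the
#' untiled run for any tiling; tiling exists to bound per-run memory on
#' large extents.
#'
#' @param cube A [weather_cube()].
#' @param params A [species_params()].
#' @param config A [run_config()]; `config$n_tiles` is overridden by
#'   `n_tiles` when supplied.
#' @param n_tiles Number of tiles.
#' @return A `pheno_grid_run`, identical to `run_grid(cube, params,
#'   config)`.
#' @export
tile_and_mosaic <- function(cube, params, config = run_config(),
                            n_tiles = config$n_tiles) {
  n_tiles <- as.integer(n_tiles)
  stopifnot(n_tiles >= 1L)
  if (n_tiles == 1L) return(run_grid(cube, params, config))

  kr <- floor(sqrt(n_tiles))
  while (n_tiles %% kr != 0L) kr <- kr - 1L
  kc <- n_tiles %/% kr
  row_chunks <- .split_indices(cube$nrow, min(kr, cube$nrow))
  col_chunks <- .split_indices(cube$ncol, min(kc, cube$ncol))

  full <- NULL
  for (rc in row_chunks) for (cc in col_chunks) {
    sub <- run_grid(.subset_cube(cube, rc, cc), params, config)
    if (is.null(full)) full <- .alloc_like(sub, cube)
    full <- .paste_tile(full, sub, rc, cc)
  }
  full$geo <- cube$geo
  full
}

.split_indices <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

.alloc_like <- function(sub, cube) {
  grow <- function(a) {
    d <- dim(a)
    d[1L] <- cube$nrow; d[2L] <- cube$ncol
    array(NA_real_, d, dimnames = dimnames(a))
  }
  full <- sub
  for (f in c("accum_dd", "stage_code", "pop_frac", "cold_accum",
              "heat_accum", "cold_class", "heat_class", "all_class",
              "voltinism_by_cohort", "voltinism", "missing_days"))
    full[[f]] <- grow(sub[[f]])
  full$events <- lapply(sub$events, function(ev) lapply(ev, grow))
  full$masked <- lapply(sub$masked, function(mk) list(
    stage_code = grow(mk$stage_code),
    voltinism = grow(mk$voltinism),
    events = lapply(mk$events, function(ev) lapply(ev, grow))))
  full
}

.paste_tile <- function(full, sub, rc, cc) {
  put <- function(dst, src) {
    nd <- length(dim(dst))
    if (nd == 2L) dst[rc, cc] <- src
    else if (nd == 3L) dst[rc, cc, ] <- src
    else dst[rc, cc, , ] <- src
    dst
  }
  for (f in c("accum_dd", "stage_code", "pop_frac", "cold_accum",
              "heat_accum", "cold_class", "heat_class", "all_class",
              "voltinism_by_cohort", "voltinism", "missing_days"))
    full[[f]] <- put(full[[f]], sub[[f]])
  for (e in names(sub$events)) for (w in names(sub$events[[e]]))
    full$events[[e]][[w]] <- put(full$events[[e]][[w]],
                                 sub$events[[e]][[w]])
  for (m in names(sub$masked)) {
    full$masked[[m]]$stage_code <- put(full$masked[[m]]$stage_code,
                                       sub$masked[[m]]$stage_code)
    full$masked[[m]]$voltinism <- put(full$masked[[m]]$voltinism,
                                      sub$masked[[m]]$voltinism)
    for (e in names(sub$masked[[m]]$events))
      for (w in names(sub$masked[[m]]$events[[e]]))
        full$masked[[m]]$events[[e]][[w]] <-
          put(full$masked[[m]]$events[[e]][[w]],
              sub$masked[[m]]$events[[e]][[w]])
  }
  full
}
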