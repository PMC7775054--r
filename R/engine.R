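# Cohort phenology engine: daily time-step advancement of life stage,
# within-stage degree-days, generation count, and phenological event days.
# One vectorized stepper (over grid cells) backs both the point-wise API
# and the raster pipeline, so a grid cell and a point run can never drift.

# stage slots used in event tables: overwintering + the four true stages
.event_slots <- c("ow", .stage_names)

#' Life-stage cycle for a species
#'
#' Returns the order in which stages are visited, starting from the
#' separately parameterized overwintering stage. Development always
#' follows egg -> larva -> pupa -> adult -> egg; the overwintering stage
#' (of whichever type) completes its cohort-specific degree-day
#' requirement and hands over to the next stage in the cycle. The
#' generation counter increments on every entry into the egg stage
#' (oviposition), including emergence of an overwintering adult.
#'
#' @param params A [species_params] object.
#' @return Character vector of length 5: `"overwintering"` followed by the
#'   four stages in the order they are entered.
#' @examples
#' p <- load_params(system.file("extdata", "epiphyas_postvittana.txt",
#'                              package = "phenorisk"))
#' stage_cycle(p)  # overwintering (larva), pupa, adult, egg, larva
#' @export
stage_cycle <- function(params) {
  stopifnot(inherits(params, "species_params"))
  i <- match(params$ow_stage, .stage_names)
  c("overwintering", .stage_names[(seq_len(4) + i - 1L) %% 4L + 1L])
}

# ---- internal vectorized state -------------------------------------------

# fresh state for n cells: all cells in the overwintering stage, gen 0
.init_cells <- function(n, params) {
  gmax <- params$max_event_generations
  list(
    n = n,
    in_ow = rep(TRUE, n),
    stage = rep(match(params$ow_stage, .stage_names), n),
    accum = numeric(n),
    generation = integer(n),
    cum_dd = numeric(n),
    missing = integer(n),
    event_day = array(NA_integer_, dim = c(n, gmax, 5L),
                      dimnames = list(NULL, paste0("g", seq_len(gmax) - 1L),
                                      .event_slots))
  )
}

# advance all cells by one day.
# dd_mat: n x 4 per-stage degree-days for the day (NA = missing weather);
# ow_dd: per-cell (or scalar) overwintering requirement; day: day-of-year.
.step_cells <- function(st, dd_mat, params, ow_dd, day) {
  n <- st$n
  gmax <- params$max_event_generations
  ow_dd <- rep_len(ow_dd, n)

  dd_active <- dd_mat[cbind(seq_len(n), st$stage)]
  miss <- is.na(dd_active)
  st$missing <- st$missing + as.integer(miss)
  ok <- !miss

  st$accum[ok] <- st$accum[ok] + dd_active[ok]
  lar <- dd_mat[, 2L]
  addc <- ok & !is.na(lar)
  st$cum_dd[addc] <- st$cum_dd[addc] + lar[addc]

  # within-stage events for the current (pre-transition) stage
  rec <- ok & !st$in_ow & st$generation < gmax
  if (any(rec)) {
    ev <- params$event_dd[st$stage[rec]]
    idx <- cbind(which(rec), st$generation[rec] + 1L, st$stage[rec] + 1L)
    hit <- st$accum[rec] >= ev & is.na(st$event_day[idx])
    if (any(hit)) st$event_day[idx[hit, , drop = FALSE]] <- day
  }

  # at most one stage transition per calendar day
  req <- ifelse(st$in_ow, ow_dd, params$stage_dd[st$stage])
  trans <- ok & st$accum >= req
  if (any(trans)) {
    # overwintering event = emergence (completion of the cohort requirement)
    owt <- trans & st$in_ow & st$generation < gmax
    if (any(owt))
      st$event_day[cbind(which(owt), st$generation[owt] + 1L, 1L)] <- day

    excess <- st$accum[trans] - req[trans]
    new_stage <- st$stage[trans] %% 4L + 1L  # next in egg->larva->pupa->adult->egg
    st$generation[trans] <- st$generation[trans] + as.integer(new_stage == 1L)
    st$in_ow[trans] <- FALSE
    st$stage[trans] <- new_stage
    st$accum[trans] <- excess

    # the carried-over excess can already satisfy the new stage's event
    w <- which(trans)
    rec2 <- st$generation[w] < gmax
    if (any(rec2)) {
      w2 <- w[rec2]
      ev2 <- params$event_dd[st$stage[w2]]
      idx2 <- cbind(w2, st$generation[w2] + 1L, st$stage[w2] + 1L)
      hit2 <- st$accum[w2] >= ev2 & is.na(st$event_day[idx2])
      if (any(hit2)) st$event_day[idx2[hit2, , drop = FALSE]] <- day
    }
  }
  st
}

# ---- point-wise API -------------------------------------------------------

#' Initial phenology state
#'
#' State of one simulated cohort member at the start of a run: in the
#' overwintering stage with zero accumulated degree-days, generation 0.
#'
#' @param params A [species_params] object.
#' @return A `pheno_state` list with fields `stage` (label), `stage_dd_accum`,
#'   `generation`, `cum_dd`, `event_day` (generations x stage-slot matrix of
#'   day-of-year), and `missing_days`.
#' @export
new_pheno_state <- function(params) {
  st <- .init_cells(1L, params)
  .cells_to_state(st, params)
}

.cells_to_state <- function(st, params) {
  structure(list(
    stage = if (st$in_ow[1L]) "overwintering" else .stage_names[st$stage[1L]],
    stage_dd_accum = st$accum[1L],
    generation = st$generation[1L],
    cum_dd = st$cum_dd[1L],
    event_day = st$event_day[1L, , , drop = TRUE],
    missing_days = st$missing[1L]
  ), class = "pheno_state")
}

.state_to_cells <- function(state, params) {
  st <- .init_cells(1L, params)
  st$in_ow[1L] <- state$stage == "overwintering"
  st$stage[1L] <- if (st$in_ow[1L]) match(params$ow_stage, .stage_names)
                  else match(state$stage, .stage_names)
  st$accum[1L] <- state$stage_dd_accum
  st$generation[1L] <- state$generation
  st$cum_dd[1L] <- state$cum_dd
  st$event_day[1L, , ] <- state$event_day
  st$missing[1L] <- state$missing_days
  st
}

#' Advance a phenology state by one day
#'
#' Adds the day's degree-days to the active stage's accumulator; when the
#' stage requirement (the cohort's own requirement for the overwintering
#' stage, `stage_dd` otherwise) is met, transitions to the next stage in
#' the cycle, carrying the excess degree-days into the new stage. At most
#' one transition occurs per calendar day. The generation counter
#' increments on adult-to-egg transitions. The first time the within-stage
#' accumulation reaches `event_dd` in a tracked generation, the day is
#' recorded in the event table (immutably). Missing weather leaves the
#' state unchanged apart from the missing-day count.
#'
#' @param state A `pheno_state` (see [new_pheno_state()]).
#' @param daily_dd Named per-stage degree-days for the day (`egg`, `larva`,
#'   `pupa`, `adult`), e.g. one row of [daily_stage_dd()]; `NA` = missing.
#' @param params A [species_params] object.
#' @param cohort_ow_dd This cohort's overwintering degree-day requirement.
#' @param day Day of year (1-based).
#' @return The updated `pheno_state`.
#' @export
advance_day <- function(state, daily_dd, params, cohort_ow_dd, day) {
  stopifnot(inherits(state, "pheno_state"))
  dd <- rbind(.as_stage_vec(daily_dd, "daily_dd"))
  st <- .state_to_cells(state, params)
  st <- .step_cells(st, dd, params, cohort_ow_dd, as.integer(day))
  .cells_to_state(st, params)
}

#' Run one cohort through a daily weather series
#'
#' Simulates a single cohort from the fixed start date (the first row of
#' `weather`, typically January 1) through the last day, sampling the
#' state every `sample_every` days (the final day is always sampled, since
#' event tables are only complete once the whole period has been seen).
#'
#' @param weather Data frame with columns `date` (consecutive calendar
#'   `Date`s), `tmin`, `tmax` (degrees C).
#' @param params A [species_params] object.
#' @param cohort_ow_dd The cohort's overwintering degree-day requirement.
#' @param sample_every Output sampling interval in days: 1, 2, 7, 10, 14,
#'   or 30.
#' @return A `cohort_trajectory`: list with `sample_day` (day-of-year),
#'   `sample_date`, `stage` and `generation` per sampled day, `cum_dd`,
#'   the final `event_day` table, `voltinism`, and `missing_days`.
#' @examples
#' p <- load_params(system.file("extdata", "epiphyas_postvittana.txt",
#'                              package = "phenorisk"))
#' w <- data.frame(date = seq(as.Date("2018-01-01"), by = 1, length.out = 365),
#'                 tmin = 12.2, tmax = 22.2)  # constant 10 DDC/day
#' tr <- run_cohort(w, p, cohort_ow_dd = 210)
#' voltinism(tr)  # 5 generations
#' @export
run_cohort <- function(weather, params, cohort_ow_dd, sample_every = 1L) {
  .check_weather_df(weather)
  sample_every <- .check_sample_every(sample_every)
  ndays <- nrow(weather)
  samp <- .sample_indices(ndays, sample_every)
  doy <- as.POSIXlt(weather$date)$yday + 1L

  st <- .init_cells(1L, params)
  out_stage <- character(length(samp))
  out_gen <- integer(length(samp))
  out_cum <- numeric(length(samp))
  k <- 1L
  for (i in seq_len(ndays)) {
    dd <- daily_stage_dd(weather$tmin[i], weather$tmax[i], params)
    st <- .step_cells(st, dd, params, cohort_ow_dd, doy[i])
    if (k <= length(samp) && samp[k] == i) {
      out_stage[k] <- if (st$in_ow[1L]) "overwintering"
                      else .stage_names[st$stage[1L]]
      out_gen[k] <- st$generation[1L]
      out_cum[k] <- st$cum_dd[1L]
      k <- k + 1L
    }
  }
  structure(list(
    sample_day = doy[samp],
    sample_date = weather$date[samp],
    stage = out_stage,
    generation = out_gen,
    cum_dd = out_cum,
    event_day = st$event_day[1L, , , drop = TRUE],
    voltinism = st$generation[1L],
    missing_days = st$missing[1L],
    cohort_ow_dd = cohort_ow_dd
  ), class = "cohort_trajectory")
}

#' Final generation count of a completed trajectory
#'
#' If the run spans an entire year this is the potential voltinism: the
#' number of ovipositions (adult to egg transitions) completed.
#'
#' @param traj A `cohort_trajectory` from [run_cohort()].
#' @return Integer number of generations.
#' @export
voltinism <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  traj$voltinism
}

#' Combine per-cohort trajectories into a population summary
#'
#' Uses the cohort weights to compute, for each sampled day, the fraction
#' of the population in every (generation, stage) combination, and for
#' each tracked generation and stage the earliest and average day-of-year
#' on which the phenological event occurs across cohorts. The average is
#' weighted by cohort population fraction by default (set
#' `weighted = FALSE` for a plain mean) and rounded to the nearest day.
#' Stage/generation composition of the middle cohort is kept separately,
#' as the single-cohort view used for stage maps.
#'
#' @param trajectories List of `cohort_trajectory` objects, one per cohort,
#'   sharing an identical sampling grid.
#' @param cohorts The matching `cohort_set`.
#' @param weighted Weight the average event day by cohort fraction?
#' @return A `population_summary`: list with `composition` (data frame:
#'   `sample_day`, `generation`, `stage`, `fraction`), `events` (data
#'   frame: `generation`, `stage`, `earliest`, `average`), `middle`
#'   (middle-cohort trajectory), and `voltinism` (per-cohort vector).
#' @export
combine_cohorts <- function(trajectories, cohorts, weighted = TRUE) {
  stopifnot(inherits(cohorts, "cohort_set"),
            length(trajectories) == nrow(cohorts))
  days <- trajectories[[1L]]$sample_day
  for (tr in trajectories)
    if (!identical(tr$sample_day, days))
      stop("cohort trajectories have mismatched sampling grids",
           call. = FALSE)
  w <- cohorts$weight

  comp <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(sample_day = tr$sample_day, generation = tr$generation,
               stage = tr$stage, weight = w[i])
  }))
  composition <- stats::aggregate(weight ~ sample_day + generation + stage,
                                  data = comp, FUN = sum)
  names(composition)[names(composition) == "weight"] <- "fraction"
  composition <- composition[order(composition$sample_day,
                                   composition$generation), ]
  rownames(composition) <- NULL

  gmax <- dim(trajectories[[1L]]$event_day)[1L]
  ev <- do.call(rbind, lapply(seq_len(gmax), function(g) {
    do.call(rbind, lapply(seq_along(.event_slots), function(s) {
      dvec <- vapply(trajectories,
                     function(tr) as.numeric(tr$event_day[g, s]), numeric(1))
      set <- !is.na(dvec)
      if (!any(set)) return(NULL)
      avg <- if (weighted) stats::weighted.mean(dvec[set], w[set])
             else mean(dvec[set])
      data.frame(generation = g - 1L, stage = .event_slots[s],
                 earliest = min(dvec[set]),
                 average = round(avg))
    }))
  }))
  if (is.null(ev))
    ev <- data.frame(generation = integer(), stage = character(),
                     earliest = numeric(), average = numeric())

  structure(list(
    composition = composition,
    events = ev,
    middle = trajectories[[middle_cohort(cohorts)]],
    voltinism = vapply(trajectories, voltinism, integer(1))
  ), class = "population_summary")
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat("<cohort_trajectory> ow requirement", x$cohort_ow_dd, "DDC;",
      length(x$sample_day), "sampled days;",
      "voltinism", x$voltinism, "\n")
  invisible(x)
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>", length(x$voltinism), "cohorts; voltinism",
      paste(x$voltinism, collapse = "/"), "\n")
  if (nrow(x$events)) {
    cat("events (earliest / average day of year):\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}

# ---- shared run helpers ---------------------------------------------------

.valid_sampling <- c(1L, 2L, 7L, 10L, 14L, 30L)

.check_sample_every <- function(sample_every) {
  sample_every <- as.integer(sample_every)
  if (!sample_every %in% .valid_sampling)
    stop("sample_every must be one of ",
         paste(.valid_sampling, collapse = ", "), call. = FALSE)
  sample_every
}

# sampled day indices: 1, 1+k, 1+2k, ... and always the final day
.sample_indices <- function(ndays, sample_every) {
  s <- seq.int(1L, ndays, by = sample_every)
  if (s[length(s)] != ndays) s <- c(s, ndays)
  s
}

.check_weather_df <- function(weather) {
  if (!is.data.frame(weather) ||
      !all(c("date", "tmin", "tmax") %in% names(weather)) ||
      nrow(weather) == 0L)
    stop("weather must be a non-empty data frame with date, tmin, tmax",
         call. = FALSE)
  d <- as.integer(diff(as.Date(weather$date)))
  if (length(d) && any(d != 1L))
    stop("weather dates must be consecutive days; gaps after ",
         paste(utils::head(weather$date[which(d != 1L)], 5), collapse = ", "),
         call. = FALSE)
  invisible(weather)
}
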