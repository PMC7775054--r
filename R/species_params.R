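#' Species parameter set for phenology and climatic suitability modeling
#'
#' Builds and validates the full parameter set describing one species:
#' per-stage lower/upper developmental thresholds, stage durations in
#' degree-days, the overwintering stage, per-stage phenological event
#' thresholds, cold/heat stress thresholds and moderate/severe accumulation
#' limits, and the overwintering emergence distribution used to build
#' cohorts.
#'
#' Temperatures are stored in degrees C. When `units = "F"`, threshold
#' temperatures are first rounded to the nearest integer Fahrenheit (the
#' long-standing degree-day convention in the United States) and then
#' converted to C; degree-day quantities are converted by scale only
#' (`5/9` C degree-days per F degree-day). Celsius inputs are never rounded.
#'
#' @param name Species label (free text).
#' @param stage_ldt,stage_udt Named numeric vectors (`egg`, `larva`, `pupa`,
#'   `adult`) of lower/upper developmental thresholds, degrees C (or F, see
#'   `units`). Each stage requires `ldt < udt`.
#' @param stage_dd Named numeric vector of stage durations, degree-days C
#'   (all `> 0`).
#' @param ow_stage One of `"egg"`, `"larva"`, `"pupa"`, `"adult"`: the
#'   separately parameterized overwintering stage. Its duration is
#'   cohort-specific (see [make_cohorts()]), not taken from `stage_dd`.
#' @param event_dd Named numeric vector (`egg`, `larva`, `pupa`, `adult`) of
#'   within-stage degree-day milestones used for phenological event maps;
#'   each must lie in `[0, stage_dd]`. The overwintering-stage event fires
#'   when a cohort completes its emergence requirement, so it carries no
#'   separate threshold here.
#' @param coldstress_threshold,heatstress_threshold Stress temperature
#'   thresholds, degrees C; daily stress units are the exceedance of Tmin
#'   below (cold) or Tmax above (heat) the threshold.
#' @param coldstress_units_max1,coldstress_units_max2 Accumulated cold
#'   stress limits (degree-days C) above which most (moderate) or all
#'   (severe) individuals are expected to die; `max1 < max2`.
#' @param heatstress_units_max1,heatstress_units_max2 Heat stress limits,
#'   same semantics.
#' @param distro_mean,distro_var,xdist1,xdist2 Mean, variance, low bound,
#'   and high bound (degree-days C) of the overwintering emergence
#'   distribution.
#' @param distro_shape `"normal"` or `"lognormal"`.
#' @param calctype Degree-day method: `"average"` (simple average with
#'   horizontal cutoff) or `"triangle"` (single triangle with upper
#'   threshold).
#' @param max_event_generations Number of generations (starting from the
#'   overwintering generation 0) for which phenological events are recorded.
#' @param units `"C"` (default) or `"F"` for the temperature unit of the
#'   supplied thresholds and degree-day values.
#' @return An object of class `species_params`.
#' @examples
#' p <- load_params(system.file("extdata", "epiphyas_postvittana.txt",
#'                              package = "phenorisk"))
#' p$stage_dd       # 127, 408, 128, 71 DDC
#' sum(p$stage_dd)  # full-generation requirement, 734 DDC
#' @export
species_params <- function(name,
                           stage_ldt, stage_udt, stage_dd,
                           ow_stage,
                           event_dd,
                           coldstress_threshold,
                           coldstress_units_max1, coldstress_units_max2,
                           heatstress_threshold,
                           heatstress_units_max1, heatstress_units_max2,
                           distro_mean, distro_var, xdist1, xdist2,
                           distro_shape = c("normal", "lognormal"),
                           calctype = c("triangle", "average"),
                           max_event_generations = 4L,
                           units = c("C", "F")) {
  units <- match.arg(units)
  distro_shape <- match.arg(distro_shape)
  calctype <- match.arg(calctype)

  stage_ldt <- .as_stage_vec(stage_ldt, "stage_ldt")
  stage_udt <- .as_stage_vec(stage_udt, "stage_udt")
  stage_dd <- .as_stage_vec(stage_dd, "stage_dd")
  event_dd <- .as_stage_vec(event_dd, "event_dd")

  if (units == "F") {
    f2c <- function(f) (round(f) - 32) * 5 / 9   # integer-F convention
    dd_f2c <- function(dd) dd * 5 / 9
    stage_ldt <- f2c(stage_ldt)
    stage_udt <- f2c(stage_udt)
    coldstress_threshold <- f2c(coldstress_threshold)
    heatstress_threshold <- f2c(heatstress_threshold)
    stage_dd <- dd_f2c(stage_dd)
    event_dd <- dd_f2c(event_dd)
    coldstress_units_max1 <- dd_f2c(coldstress_units_max1)
    coldstress_units_max2 <- dd_f2c(coldstress_units_max2)
    heatstress_units_max1 <- dd_f2c(heatstress_units_max1)
    heatstress_units_max2 <- dd_f2c(heatstress_units_max2)
    distro_mean <- dd_f2c(distro_mean)
    distro_var <- distro_var * (5 / 9)^2
    xdist1 <- dd_f2c(xdist1)
    xdist2 <- dd_f2c(xdist2)
  }

  obj <- structure(list(
    name = as.character(name),
    stage_ldt = stage_ldt,
    stage_udt = stage_udt,
    stage_dd = stage_dd,
    ow_stage = ow_stage,
    event_dd = event_dd,
    coldstress_threshold = coldstress_threshold,
    coldstress_units_max1 = coldstress_units_max1,
    coldstress_units_max2 = coldstress_units_max2,
    heatstress_threshold = heatstress_threshold,
    heatstress_units_max1 = heatstress_units_max1,
    heatstress_units_max2 = heatstress_units_max2,
    distro_mean = distro_mean,
    distro_var = distro_var,
    xdist1 = xdist1,
    xdist2 = xdist2,
    distro_shape = distro_shape,
    calctype = calctype,
    max_event_generations = as.integer(max_event_generations)
  ), class = "species_params")
  validate_species_params(obj)
}

.as_stage_vec <- function(x, what) {
  if (is.null(names(x)) && length(x) == 4L) names(x) <- .stage_names
  if (!all(.stage_names %in% names(x))) {
    stop(what, " must be named with stages ",
         paste(.stage_names, collapse = ", "), call. = FALSE)
  }
  vapply(.stage_names, function(s) as.numeric(x[[s]]), numeric(1))
}

#' Validate a species parameter set
#'
#' Checks the structural invariants of a [species_params] object and
#' returns it invisibly unchanged, or stops with an error naming the
#' violated invariant.
#'
#' @param p A `species_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_species_params <- function(p) {
  fail <- function(...) stop("invalid species parameters: ", ...,
                             call. = FALSE)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  for (f in c("stage_ldt", "stage_udt", "stage_dd", "event_dd"))
    if (!num_ok(p[[f]]) || length(p[[f]]) != 4L) fail(f, " must be 4 finite values")
  if (!all(p$stage_ldt < p$stage_udt))
    fail("stage_ldt < stage_udt must hold for every stage")
  if (!all(p$stage_dd > 0))
    fail("stage_dd must be > 0 for every stage")
  if (!p$ow_stage %in% .stage_names)
    fail("ow_stage must be one of ", paste(.stage_names, collapse = ", "))
  if (!all(p$event_dd >= 0 & p$event_dd <= p$stage_dd))
    fail("event_dd must satisfy 0 <= event_dd <= stage_dd for every stage")
  if (!(p$coldstress_units_max1 < p$coldstress_units_max2))
    fail("coldstress_units_max1 < coldstress_units_max2 must hold")
  if (!(p$heatstress_units_max1 < p$heatstress_units_max2))
    fail("heatstress_units_max1 < heatstress_units_max2 must hold")
  if (!(p$xdist1 <= p$distro_mean && p$distro_mean <= p$xdist2))
    fail("xdist1 <= distro_mean <= xdist2 must hold")
  if (!(p$distro_var >= 0))
    fail("distro_var must be >= 0")
  if (p$max_event_generations < 1L)
    fail("max_event_generations must be >= 1")
  invisible(p)
}

# keys of the flat parameter-file schema, in canonical order
.param_keys <- list(
  stage_ldt = c(egg = "eggLDT", larva = "larvaeLDT",
                pupa = "pupaeLDT", adult = "adultLDT"),
  stage_udt = c(egg = "eggUDT", larva = "larvaeUDT",
                pupa = "pupaeUDT", adult = "adultUDT"),
  stage_dd = c(egg = "eggDD", larva = "larvaeDD",
               pupa = "pupDD", adult = "adultDD"),
  event_dd = c(egg = "eggEventDD", larva = "larvaeEventDD",
               pupa = "pupaeEventDD", adult = "adultEventDD"),
  scalars = c("coldstress_threshold", "coldstress_units_max1",
              "coldstress_units_max2", "heatstress_threshold",
              "heatstress_units_max1", "heatstress_units_max2",
              "distro_mean", "distro_var", "xdist1", "xdist2")
)

#' Load a species parameter file
#'
#' Reads a flat key-value species parameter file (Debian-control/DCF
#' dialect: one `key: value` per line) whose keys are the standard
#' parameter codes (`eggLDT`, `larvaeDD`, `coldstress_units_max1`,
#' `distro_mean`, ...) plus `name`, `owstage`, `distro_shape`, `calctype`
#' and optional `units` (`C`, the default, or `F`) and
#' `max_event_generations`. The overwintering-stage duration codes
#' (`OWlarvaeDD` etc.) and `OWEventDD` take the value `varies` (or are
#' omitted): the duration is cohort-specific and the overwintering event
#' is emergence itself.
#'
#' Parameter files for *Epiphyas postvittana* (light brown apple moth) and
#' *Neoleucinodes elegantalis* (small tomato borer) ship with the package
#' under `system.file("extdata", package = "phenorisk")`.
#'
#' @param path Path to the parameter file.
#' @return A validated [species_params] object (temperatures in C).
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  dcf <- read.dcf(path)
  if (nrow(dcf) != 1L) stop("parameter file must contain one record: ",
                            path, call. = FALSE)
  kv <- stats::setNames(as.list(dcf[1L, ]), colnames(dcf))

  need <- function(key) {
    if (is.null(kv[[key]]) || is.na(kv[[key]]))
      stop("parameter file is missing required key '", key, "'",
           call. = FALSE)
    kv[[key]]
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(need(key)))
    if (is.na(v)) stop("key '", key, "' must be numeric, got '",
                       kv[[key]], "'", call. = FALSE)
    v
  }
  grab <- function(codes) stats::setNames(vapply(codes, num, numeric(1)),
                                          names(codes))

  scalars <- lapply(stats::setNames(nm = .param_keys$scalars), num)
  species_params(
    name = need("name"),
    stage_ldt = grab(.param_keys$stage_ldt),
    stage_udt = grab(.param_keys$stage_udt),
    stage_dd = grab(.param_keys$stage_dd),
    ow_stage = .normalize_stage(need("owstage")),
    event_dd = grab(.param_keys$event_dd),
    coldstress_threshold = scalars$coldstress_threshold,
    coldstress_units_max1 = scalars$coldstress_units_max1,
    coldstress_units_max2 = scalars$coldstress_units_max2,
    heatstress_threshold = scalars$heatstress_threshold,
    heatstress_units_max1 = scalars$heatstress_units_max1,
    heatstress_units_max2 = scalars$heatstress_units_max2,
    distro_mean = scalars$distro_mean,
    distro_var = scalars$distro_var,
    xdist1 = scalars$xdist1,
    xdist2 = scalars$xdist2,
    distro_shape = tolower(need("distro_shape")),
    calctype = tolower(need("calctype")),
    max_event_generations =
      if (!is.null(kv[["max_event_generations"]]))
        as.integer(kv[["max_event_generations"]]) else 4L,
    units = if (!is.null(kv[["units"]])) toupper(kv[["units"]]) else "C"
  )
}

.normalize_stage <- function(s) {
  s <- tolower(trimws(s))
  map <- c(egg = "egg", eggs = "egg",
           larva = "larva", larvae = "larva",
           pupa = "pupa", pupae = "pupa",
           adult = "adult", adults = "adult")
  if (!s %in% names(map)) stop("unknown life stage: '", s, "'",
                               call. = FALSE)
  unname(map[[s]])
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>", x$name, "\n")
  tab <- data.frame(stage = .stage_names,
                    ldt = x$stage_ldt, udt = x$stage_udt,
                    dd = x$stage_dd, event_dd = x$event_dd,
                    row.names = NULL)
  print(tab, row.names = FALSE)
  cat("overwintering stage:", x$ow_stage, "\n")
  cat(sprintf("cold stress: < %g C, limits %g / %g DDC\n",
              x$coldstress_threshold, x$coldstress_units_max1,
              x$coldstress_units_max2))
  cat(sprintf("heat stress: > %g C, limits %g / %g DDC\n",
              x$heatstress_threshold, x$heatstress_units_max1,
              x$heatstress_units_max2))
  cat(sprintf("emergence: %s(mean %g, var %g) on [%g, %g] DDC\n",
              x$distro_shape, x$distro_mean, x$distro_var,
              x$xdist1, x$xdist2))
  cat("degree-day method:", x$calctype, "\n")
  invisible(x)
}
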