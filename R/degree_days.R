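#' Daily degree-days: simple average with horizontal upper cutoff
#'
#' Computes degree-days for one day from the daily minimum and maximum
#' temperature using the simple average method with an upper threshold and a
#' horizontal cutoff: the daily mean temperature is clamped to the
#' `[ldt, udt]` interval before subtracting the lower developmental threshold.
#'
#' All arguments are vectorized and recycled to a common length, so the
#' function applies equally to a single day, a temperature series, or a
#' flattened raster layer.
#'
#' @param tmin,tmax Daily minimum and maximum temperature, degrees C. Where
#'   `tmin > tmax` the pair is swapped with a warning. Non-finite inputs
#'   propagate as `NA` (missing weather never counts as zero development).
#' @param ldt,udt Lower and upper developmental thresholds, degrees C
#'   (`ldt < udt`).
#' @return Degree-days C, in `[0, udt - ldt]`, with `NA` for missing inputs.
#' @seealso [dd_single_triangle()] for the single triangle method.
#' @examples
#' dd_simple_average(10, 20, ldt = 10, udt = 30)  # mean 15 -> 5 DDC
#' dd_simple_average(30, 40, ldt = 10, udt = 30)  # capped at 20 DDC
#' @export
dd_simple_average <- function(tmin, tmax, ldt, udt) {
  stopifnot(all(ldt < udt))
  tt <- .repair_minmax(tmin, tmax)
  m <- (tt$tmin + tt$tmax) / 2
  dd <- pmin(pmax(m, ldt), udt) - ldt
  dd[!is.finite(m)] <- NA_real_
  dd
}

#' Daily degree-days: single triangle method with upper threshold
#'
#' Models the daily temperature trajectory as a triangle rising from `tmin`
#' to `tmax` and back over 24 h, and returns the mean of the trajectory
#' clipped to `[ldt, udt]`, minus `ldt`. The area above the upper threshold
#' is removed (horizontal cutoff), not reflected. The method is the standard
#' close approximation to the sine-curve calculation.
#'
#' Closed form: with `a = tmin`, `b = tmax`,
#' * `b <= ldt` gives 0; `a >= udt` gives `udt - ldt`;
#' * a constant day (`a == b`) gives `clamp(a, ldt, udt) - ldt`, floored at 0;
#' * otherwise the base area is `(a + b)/2 - ldt` when `a >= ldt`, else
#'   `(b - ldt)^2 / (2 (b - a))`; when `b > udt` the cap
#'   `(b - udt)^2 / (2 (b - a))` is subtracted; the result is floored at 0.
#'
#' @inheritParams dd_simple_average
#' @return Degree-days C, in `[0, udt - ldt]`, `NA` for missing inputs.
#' @examples
#' dd_single_triangle(10, 30, ldt = 20, udt = 40)  # 2.5 DDC
#' dd_single_triangle(20, 40, ldt = 10, udt = 30)  # 17.5 DDC
#' @export
dd_single_triangle <- function(tmin, tmax, ldt, udt) {
  stopifnot(all(ldt < udt))
  tt <- .repair_minmax(tmin, tmax)
  a <- tt$tmin
  b <- tt$tmax
  n <- max(length(a), length(b), length(ldt), length(udt))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ldt <- rep_len(ldt, n); udt <- rep_len(udt, n)

  dd <- numeric(n)
  miss <- !is.finite(a) | !is.finite(b)
  flat <- !miss & a == b
  tri <- !miss & !flat

  # constant-temperature limit of the triangle
  dd[flat] <- pmax(pmin(a[flat], udt[flat]) - ldt[flat], 0)

  base <- ifelse(a[tri] >= ldt[tri],
                 (a[tri] + b[tri]) / 2 - ldt[tri],
                 (b[tri] - ldt[tri])^2 / (2 * (b[tri] - a[tri])))
  base[b[tri] <= ldt[tri]] <- 0
  cap <- ifelse(b[tri] > udt[tri],
                (b[tri] - udt[tri])^2 / (2 * (b[tri] - a[tri])),
                0)
  dd[tri] <- pmax(base - cap, 0)
  # fully supra-optimal day
  hot <- tri & a >= udt
  dd[hot] <- udt[hot] - ldt[hot]
  dd <- pmin(dd, udt - ldt)
  dd[miss] <- NA_real_
  dd
}

#' Per-stage daily degree-days for a parameterized species
#'
#' Applies the degree-day method named by `params$calctype` with each life
#' stage's own developmental thresholds. When all stages share thresholds
#' (the common case for the shipped species) the four values are identical.
#'
#' @param tmin,tmax Daily minimum and maximum temperature, degrees C
#'   (vectorized; e.g. all cells of a grid for one day).
#' @param params A [species_params] object.
#' @return A numeric matrix with one row per input element and columns
#'   `egg`, `larva`, `pupa`, `adult` (degree-days C). For scalar input the
#'   matrix has a single row.
#' @export
daily_stage_dd <- function(tmin, tmax, params) {
  stopifnot(inherits(params, "species_params"))
  fun <- switch(params$calctype,
                average = dd_simple_average,
                triangle = dd_single_triangle,
                stop("unknown degree-day calculation method: ",
                     params$calctype, call. = FALSE))
  n <- max(length(tmin), length(tmax))
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, .stage_names))
  for (s in .stage_names) {
    out[, s] <- fun(tmin, tmax, params$stage_ldt[[s]], params$stage_udt[[s]])
  }
  out
}

.stage_names <- c("egg", "larva", "pupa", "adult")

# swap tmin/tmax pairs that arrive inverted; warn once per call
.repair_minmax <- function(tmin, tmax) {
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  bad <- !is.na(tmin) & !is.na(tmax) & tmin > tmax
  if (any(bad)) {
    warning(sum(bad), " day(s) with tmin > tmax; values swapped",
            call. = FALSE)
    tmp <- tmin[bad]
    tmin[bad] <- tmax[bad]
    tmax[bad] <- tmp
  }
  list(tmin = tmin, tmax = tmax)
}
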