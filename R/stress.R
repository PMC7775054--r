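#' Daily cold and heat stress units
#'
#' Cold stress units for a day are the exceedance of the daily minimum
#' temperature below the cold stress threshold; heat stress units are the
#' exceedance of the daily maximum above the heat stress threshold. A
#' single threshold pair applies to all life stages, and stress
#' accumulates linearly across the whole period of interest (consecutive
#' days carry no extra weight).
#'
#' @param tmin,tmax Daily minimum/maximum temperature, degrees C
#'   (vectorized). `NA` propagates.
#' @param threshold Stress temperature threshold, degrees C.
#' @return Non-negative stress units (degree-days C).
#' @examples
#' daily_cold_stress(-7, 3)  # 10 units
#' daily_heat_stress(40, 31) # 9 units
#' @export
daily_cold_stress <- function(tmin, threshold) {
  pmax(threshold - tmin, 0)
}

#' @rdname daily_cold_stress
#' @export
daily_heat_stress <- function(tmax, threshold) {
  pmax(tmax - threshold, 0)
}

#' Accumulate daily stress units over a run
#'
#' Running (cumulative) sum of daily stress units. Accumulation never
#' resets within a run; `NA` days contribute nothing but are tracked by
#' the caller as missing.
#'
#' @param units Numeric vector (or matrix with days in columns) of daily
#'   stress units.
#' @return Object of the same shape containing the running totals.
#' @export
accumulate_stress <- function(units) {
  if (is.matrix(units)) {
    u <- units
    u[is.na(u)] <- 0
    t(apply(u, 1L, cumsum))
  } else {
    u <- units
    u[is.na(u)] <- 0
    cumsum(u)
  }
}

#' Classify accumulated stress against moderate and severe limits
#'
#' Compares an accumulated stress total to the user-defined moderate
#' (`max1`) and severe (`max2`) limits. A cell is excluded only when its
#' accumulation strictly exceeds a limit, so boundary equality still
#' counts as not excluded.
#'
#' @param accum Accumulated stress units (vectorized).
#' @param max1,max2 Moderate and severe limits, `max1 < max2`.
#' @return Integer vector of exclusion codes: 0 = none, 1 = moderate
#'   exclusion, 2 = severe exclusion (see [exclusion_levels]).
#' @examples
#' classify_exclusion(c(0, 900, 1130), 875, 1125)  # 0 1 2
#' @export
classify_exclusion <- function(accum, max1, max2) {
  stopifnot(max1 < max2)
  out <- integer(length(accum))
  out[accum > max1] <- 1L
  out[accum > max2] <- 2L
  out[is.na(accum)] <- NA_integer_
  if (!is.null(dim(accum))) dim(out) <- dim(accum)
  out
}

#' Exclusion class codes and labels
#'
#' Integer codes used throughout for stress exclusion classes, and the
#' labels used on maps.
#' @format Named integer vector.
#' @export
exclusion_levels <- c(none = 0L, `excl.-moderate` = 1L, `excl.-severe` = 2L)

#' Combine cold and heat exclusion classes
#'
#' The all-stress class of a cell is the more severe of its cold and heat
#' classes.
#'
#' @param cold_class,heat_class Integer exclusion codes (same shape).
#' @return Integer codes of the combined class.
#' @export
combine_exclusion <- function(cold_class, heat_class) {
  pmax(cold_class, heat_class)
}

#' Mask a phenology layer by stress exclusion
#'
#' Replaces values of a gridded phenology output in excluded cells by
#' sentinel codes (severe -> `-2`, moderate -> `-1`), leaving other cells
#' untouched. Two map variants are standard: one applying the severe
#' exclusion only, and one applying both severe and moderate exclusions.
#' Accumulated degree-day layers are never masked.
#'
#' @param pheno_layer Numeric matrix/array of phenology values.
#' @param exclusion Integer exclusion codes, same dimensions (typically
#'   the all-stress class of the last day).
#' @param mode `"severe_only"` or `"severe_and_moderate"`.
#' @return The masked layer.
#' @export
apply_exclusion_mask <- function(pheno_layer,
                                 exclusion,
                                 mode = c("severe_only",
                                          "severe_and_moderate")) {
  mode <- match.arg(mode)
  if (!identical(dim(pheno_layer), dim(exclusion)) &&
      length(pheno_layer) != length(exclusion))
    stop("phenology layer and exclusion grid have mismatched geometry",
         call. = FALSE)
  out <- pheno_layer
  out[!is.na(exclusion) & exclusion == 2L] <- -2
  if (mode == "severe_and_moderate")
    out[!is.na(exclusion) & exclusion == 1L] <- -1
  out
}

#' Rescale a stress accumulation grid to [0, 1000]
#'
#' Linear rescale by the grid maximum, for display on a common 0-1000
#' scale. An all-zero grid maps to all zeros.
#'
#' @param accum Non-negative numeric vector/matrix of accumulated stress.
#' @return Values rescaled so the maximum maps to 1000.
#' @export
scale_stress <- function(accum) {
  m <- max(accum, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) return(accum * 0)
  accum / m * 1000
}
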