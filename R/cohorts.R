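#' Discretize the overwintering emergence distribution into cohorts
#'
#' Splits the emergence interval `[xdist1, xdist2]` into `n` equal-width
#' bins. Each cohort's overwintering degree-day requirement is the bin
#' midpoint, and its population weight is the probability mass of the
#' emergence distribution (truncated to the interval) within the bin,
#' renormalized to sum to one. Individuals within a cohort develop in
#' synchrony; the cohort weights initialize the population distribution
#' that is carried through all subsequent stages and generations.
#'
#' For `distro_shape = "normal"` the distribution is
#' Normal(`distro_mean`, `distro_var`) truncated to the interval. For
#' `"lognormal"` the variate shifted by `xdist1` is lognormal with the
#' stated mean and variance (converted internally to log-scale
#' parameters). `n = 1` returns a single cohort at `distro_mean` with
#' weight 1.
#'
#' @param params A [species_params] object.
#' @param n Number of cohorts (positive integer).
#' @return An object of class `cohort_set`: a data frame with columns
#'   `emergence_dd` (strictly increasing, degree-days C) and `weight`
#'   (positive, summing to 1), one row per cohort.
#' @examples
#' p <- load_params(system.file("extdata", "epiphyas_postvittana.txt",
#'                              package = "phenorisk"))
#' make_cohorts(p, 7)  # the standard seven-cohort approximation
#' @export
make_cohorts <- function(params, n) {
  stopifnot(inherits(params, "species_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)

  if (n == 1L) {
    return(.new_cohort_set(params$distro_mean, 1))
  }
  if (params$distro_var == 0)
    stop("degenerate emergence distribution: distro_var = 0 requires n = 1",
         call. = FALSE)

  x1 <- params$xdist1
  x2 <- params$xdist2
  if (!(x2 > x1)) stop("xdist2 must exceed xdist1 for n > 1", call. = FALSE)
  edges <- seq(x1, x2, length.out = n + 1L)
  mids <- (edges[-1L] + edges[-(n + 1L)]) / 2

  cdf <- emergence_cdf(params)
  mass <- diff(cdf(edges))
  total <- cdf(x2) - cdf(x1)
  if (!is.finite(total) || total <= 0)
    stop("emergence distribution has no mass on [xdist1, xdist2]",
         call. = FALSE)
  w <- mass / sum(mass)
  if (any(w <= 0))
    stop("cohort weights must all be positive; widen bounds or reduce n",
         call. = FALSE)
  .new_cohort_set(mids, w)
}

#' Cumulative distribution function of the emergence distribution
#'
#' Returns the (untruncated) CDF implied by a species' emergence
#' parameters, used to assign probability mass to cohort bins and as the
#' reference for convergence checks.
#'
#' @param params A [species_params] object.
#' @return A function mapping degree-days C to cumulative probability.
#' @keywords internal
#' @export
emergence_cdf <- function(params) {
  if (params$distro_shape == "normal") {
    m <- params$distro_mean
    s <- sqrt(params$distro_var)
    function(x) stats::pnorm(x, mean = m, sd = s)
  } else {
    # shifted lognormal: X - xdist1 ~ LN(mu, sigma) with the stated
    # mean/variance on the natural scale
    m <- params$distro_mean - params$xdist1
    if (m <= 0)
      stop("lognormal emergence requires distro_mean > xdist1",
           call. = FALSE)
    v <- params$distro_var
    sigma2 <- log(1 + v / m^2)
    mu <- log(m) - sigma2 / 2
    x1 <- params$xdist1
    function(x) stats::plnorm(pmax(x - x1, 0), meanlog = mu,
                              sdlog = sqrt(sigma2))
  }
}

.new_cohort_set <- function(emergence_dd, weight) {
  stopifnot(length(emergence_dd) == length(weight),
            !is.unsorted(emergence_dd, strictly = TRUE))
  structure(data.frame(emergence_dd = emergence_dd, weight = weight),
            class = c("cohort_set", "data.frame"))
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("<cohort_set>", nrow(x), "cohort(s)\n")
  NextMethod()
  invisible(x)
}

#' Index of the middle cohort
#'
#' Stage/generation summary maps are produced for the middle cohort only,
#' since under a roughly symmetric emergence distribution it represents
#' the largest share of the population.
#'
#' @param cohorts A `cohort_set`.
#' @return Integer index `ceiling(n / 2)`.
#' @export
middle_cohort <- function(cohorts) {
  as.integer(ceiling(nrow(cohorts) / 2))
}
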