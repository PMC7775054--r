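# shared fixtures and independent oracles

ep_params <- function() {
  load_params(system.file("extdata", "epiphyas_postvittana.txt",
                          package = "phenorisk"))
}

ne_params <- function() {
  load_params(system.file("extdata", "neoleucinodes_elegantalis.txt",
                          package = "phenorisk"))
}

const_weather <- function(temp, days = 365L,
                          start = as.Date("2018-01-01"),
                          diurnal = 0) {
  data.frame(date = seq(start, by = 1, length.out = days),
             tmin = temp - diurnal / 2, tmax = temp + diurnal / 2)
}

# brute-force oracle: mean of the clipped triangular daily temperature
# trajectory at 1-minute resolution (rise tmin->tmax over 12 h, fall back)
tri_oracle <- function(tmin, tmax, ldt, udt, n = 1440L) {
  tt <- seq(0, 1, length.out = n + 1L)[-1L] - 1 / (2 * n)  # midpoints
  up <- tt <= 0.5
  temp <- ifelse(up, tmin + (tmax - tmin) * tt / 0.5,
                 tmax - (tmax - tmin) * (tt - 0.5) / 0.5)
  mean(pmax(pmin(temp, udt), ldt) - ldt)
}

# per-bin truncated-distribution mass by numeric integration (independent
# of the pnorm/plnorm-difference route used by make_cohorts)
bin_mass_oracle <- function(density, lower, upper, x1, x2) {
  total <- stats::integrate(density, x1, x2)$value
  stats::integrate(density, lower, upper)$value / total
}

# mean of a distribution truncated to [x1, x2], by numeric integration
truncated_mean_oracle <- function(density, x1, x2) {
  num <- stats::integrate(function(x) x * density(x), x1, x2)$value
  den <- stats::integrate(density, x1, x2)$value
  num / den
}

month_of_year <- function(year) {
  rep(1:12, times = c(31, if ((year %% 4 == 0 && year %% 100 != 0) ||
                              year %% 400 == 0) 29 else 28,
                      31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
}

# smallest usable gradient cube for pipeline tests
small_gradient_cube <- function(n_days = 365L, n_rows = 8L, n_cols = 6L) {
  generate_weather(synth_spec(n_rows = n_rows, n_cols = n_cols,
                              n_days = n_days))
}
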