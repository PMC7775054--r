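test_that("flat specs give constant cubes; seeds make noise reproducible", {
  spec <- synth_spec(n_rows = 3, n_cols = 3, n_days = 30, base_mean = 20,
                     lat_gradient = 0, seasonal_amplitude = 0,
                     diurnal_range = 10)
  cube <- generate_weather(spec)
  expect_true(all(cube$tmin == 15))
  expect_true(all(cube$tmax == 25))

  noisy <- synth_spec(n_rows = 3, n_cols = 3, n_days = 30, noise_sd = 2,
                      seed = 99)
  c1 <- generate_weather(noisy)
  c2 <- generate_weather(noisy)
  expect_identical(c1$tmin, c2$tmin)
  expect_true(all(c1$tmax >= c1$tmin))
  c3 <- generate_weather(synth_spec(n_rows = 3, n_cols = 3, n_days = 30,
                                    noise_sd = 2, seed = 100))
  expect_false(identical(c1$tmin, c3$tmin))
})

test_that("seasonal cycle peaks mid-July and cools northward", {
  spec <- synth_spec(n_rows = 5, n_cols = 1, n_days = 365, base_mean = 25,
                     lat_gradient = 2, seasonal_amplitude = 15,
                     diurnal_range = 0)
  cube <- generate_weather(spec)
  south <- cube$tmax[5, 1, ]   # row n = south edge
  expect_equal(which.max(south), 196L)
  expect_equal(max(south), 25)           # base_mean on the warmest day
  # days 13 and 14 are equidistant from the mid-July peak (cosine symmetry)
  expect_true(which.min(south) %in% c(13L, 14L))
  expect_equal(south[13], south[14], tolerance = 1e-9)
  # each row is uniformly colder than the row south of it
  for (r in 1:4) expect_true(all(cube$tmax[r, 1, ] < cube$tmax[r + 1, 1, ]))
})

test_that("monthly-to-daily interpolation preserves every monthly mean", {
  yr <- 2018L
  mo <- month_of_year(yr)

  const <- monthly_to_daily(rep(12.3, 12), yr)
  expect_equal(const, rep(12.3, 365))

  sine <- 10 - 12 * cos(2 * pi * (1:12 - 0.5) / 12)
  ds <- monthly_to_daily(sine, yr)
  expect_equal(as.numeric(tapply(ds, mo, mean)), sine, tolerance = 0.01)

  spike <- c(rep(5, 6), 25, rep(5, 5))
  dsp <- monthly_to_daily(spike, yr)
  expect_equal(as.numeric(tapply(dsp, mo, mean)), spike, tolerance = 0.01)

  # leap year gets 366 days
  expect_length(monthly_to_daily(sine, 2020L), 366L)

  set.seed(5)
  for (i in 1:25) {
    mm <- runif(12, -15, 30)
    dd <- monthly_to_daily(mm, yr)
    expect_lt(max(abs(as.numeric(tapply(dd, mo, mean)) - mm)), 0.0100001)
  }

  expect_error(monthly_to_daily(c(1, 2, 3), yr), "12 finite")
})
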