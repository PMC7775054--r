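test_that("weather cubes validate dates and repair inverted extremes", {
  d <- seq(as.Date("2018-01-01"), by = 1, length.out = 3)
  tmin <- array(5, c(2, 2, 3)); tmax <- array(10, c(2, 2, 3))
  cube <- weather_cube(d, tmin, tmax)
  expect_equal(cube$ndays, 3L)

  expect_error(weather_cube(d[c(1, 3, 2)], tmin, tmax), "consecutive")

  tmax_bad <- tmax; tmax_bad[1, 1, 2] <- 0  # below tmin
  expect_warning(fixed <- weather_cube(d, tmin, tmax_bad), "swapped")
  expect_equal(fixed$tmin[1, 1, 2], 0)
  expect_equal(fixed$tmax[1, 1, 2], 5)

  f <- weather_cube(d, tmin + 32, tmax + 32, units = "F")  # data not rounded
  expect_equal(f$tmin[1, 1, 1], 5 * 5 / 9)
})

test_that("per-day GeoTIFF pairs roundtrip through read_weather", {
  cube <- generate_weather(synth_spec(n_rows = 4, n_cols = 3, n_days = 10,
                                      noise_sd = 0.5))
  dir <- withr::local_tempdir()
  write_weather(cube, dir)
  back <- read_weather(dir)
  expect_equal(back$dates, cube$dates)
  expect_equal(back$tmin, cube$tmin, tolerance = 1e-5)
  expect_equal(back$tmax, cube$tmax, tolerance = 1e-5)
  expect_equal(back$geo$xres, cube$geo$xres)

  # a missing day is reported by date
  unlink(file.path(dir, paste0("tmin_", format(cube$dates[4]), ".tif")))
  expect_error(read_weather(dir), format(cube$dates[4]))
})

test_that("cropping keeps the matching window and updates geometry", {
  cube <- generate_weather(synth_spec(n_rows = 10, n_cols = 8, n_days = 4,
                                      lat_gradient = 1))
  g <- cube$geo
  # extent covering columns 3..5 and rows 2..6 by cell centers
  ext <- c(g$xmin + 2 * g$xres, g$xmin + 5 * g$xres,
           g$ymax - 6 * g$yres, g$ymax - 1 * g$yres)
  cr <- crop_cube(cube, ext)
  expect_equal(dim(cr$tmin), c(5L, 3L, 4L))
  expect_equal(cr$tmin, cube$tmin[2:6, 3:5, , drop = FALSE])
  expect_equal(cr$geo$xmin, g$xmin + 2 * g$xres)
  expect_equal(cr$geo$ymax, g$ymax - 1 * g$yres)
  expect_error(crop_cube(cube, c(1e6, 2e6, 1e6, 2e6)), "no grid cells")
})
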