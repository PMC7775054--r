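test_that("daily stress units are threshold exceedances", {
  expect_equal(daily_cold_stress(-7, 3), 10)
  expect_equal(daily_cold_stress(5, 3), 0)
  expect_equal(daily_cold_stress(3, 3), 0)   # boundary: no stress
  expect_equal(daily_heat_stress(40, 31), 9)
  expect_equal(daily_heat_stress(30, 31), 0)
  expect_equal(daily_heat_stress(32, 32), 0)
  expect_true(is.na(daily_cold_stress(NA, 3)))
})

test_that("stress accumulates linearly and never decreases", {
  expect_equal(accumulate_stress(c(10, 0, 5)), c(10, 10, 15))
  expect_equal(accumulate_stress(rep(0, 5)), rep(0, 5))
  trace <- accumulate_stress(daily_cold_stress(rep(-7, 113), 3))
  expect_equal(trace[113], 1130)
  expect_true(all(diff(trace) >= 0))
  # matrix form: one row per cell
  m <- accumulate_stress(rbind(c(1, 2, 3), c(0, 0, 1)))
  expect_equal(m, rbind(c(1, 3, 6), c(0, 0, 1)))
})

test_that("exclusion uses strictly-greater comparison at both limits", {
  expect_equal(classify_exclusion(c(0, 875, 900, 1125, 1130), 875, 1125),
               c(0L, 0L, 1L, 1L, 2L))
  expect_error(classify_exclusion(10, 100, 100))
  # class is monotone along an accumulation trace, severe within moderate
  trace <- accumulate_stress(rep(10, 113))
  cls <- classify_exclusion(trace, 875, 1125)
  expect_true(all(diff(cls) >= 0))
  expect_true(all(cls[cls == 2L] >= 1L))
  # moderate crossed on day 88, severe on day 113 at 10 units/day
  expect_equal(min(which(cls >= 1L)), 88L)
  expect_equal(min(which(cls == 2L)), 113L)
})

test_that("combined class is the worse of cold and heat", {
  expect_equal(combine_exclusion(c(0L, 1L, 2L, 0L), c(1L, 0L, 1L, 2L)),
               c(1L, 1L, 2L, 2L))
})

test_that("exclusion masks replace cells with sentinel codes", {
  ph <- matrix(as.numeric(1:9), 3)
  ex <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L), 3)
  sev <- apply_exclusion_mask(ph, ex, "severe_only")
  expect_equal(sev[, 1], c(1, 2, 3))     # untouched
  expect_equal(sev[, 2], c(4, 5, 6))     # moderate cells keep their values
  expect_equal(sev[, 3], rep(-2, 3))
  both <- apply_exclusion_mask(ph, ex, "severe_and_moderate")
  expect_equal(both[, 2], rep(-1, 3))
  expect_equal(both[, 3], rep(-2, 3))
  # identity when nothing is excluded; full mask when everything is severe
  expect_equal(apply_exclusion_mask(ph, ph * 0L, "severe_and_moderate"), ph)
  expect_true(all(apply_exclusion_mask(ph, ph * 0L + 2L, "severe_only") == -2))
  expect_error(apply_exclusion_mask(ph, ex[1:2, 1:2], "severe_only"),
               "mismatch")
})

test_that("stress scaling maps the grid maximum to 1000", {
  expect_equal(scale_stress(c(0, 500, 2000)), c(0, 250, 1000))
  expect_equal(scale_stress(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(scale_stress(7), 1000)
})
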