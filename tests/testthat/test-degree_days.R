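test_that("simple average method follows the horizontal-cutoff closed form", {
  expect_equal(dd_simple_average(10, 20, 10, 30), 5)
  expect_equal(dd_simple_average(0, 6, 7.2, 31.1), 0)
  expect_equal(dd_simple_average(30, 40, 10, 30), 20)  # capped at udt - ldt
  # vectorized over cells
  expect_equal(dd_simple_average(c(10, 0, 30), c(20, 6, 40), 10, 30),
               c(5, 0, 20))
})

test_that("single triangle method matches its closed-form examples", {
  expect_equal(dd_single_triangle(10, 30, 20, 40), 2.5)   # (30-20)^2/(2*20)
  expect_equal(dd_single_triangle(5, 7, 7.2, 31.1), 0)
  expect_equal(dd_single_triangle(20, 40, 10, 30), 17.5)  # 20 - (40-30)^2/40
  # constant-temperature day: clamp limit
  expect_equal(dd_single_triangle(8, 8, 5, 10), 3)
  expect_equal(dd_single_triangle(4, 4, 5, 10), 0)
  expect_equal(dd_single_triangle(12, 12, 5, 10), 5)
})

test_that("triangle method agrees with 1-minute integration oracle", {
  set.seed(42)
  n <- 400  # small randomized grid; the acceptance suite runs 10,000
  tmin <- runif(n, -20, 35)
  tmax <- tmin + runif(n, 0, 25)
  ldt <- runif(n, -5, 15)
  udt <- ldt + runif(n, 1, 25)
  got <- dd_single_triangle(tmin, tmax, ldt, udt)
  want <- vapply(seq_len(n),
                 function(i) tri_oracle(tmin[i], tmax[i], ldt[i], udt[i]),
                 numeric(1))
  expect_lt(max(abs(got - want)), 0.01)
})

test_that("both methods are bounded and monotone in tmin and tmax", {
  set.seed(7)
  for (f in list(dd_simple_average, dd_single_triangle)) {
    tmin <- runif(200, -15, 30)
    tmax <- tmin + runif(200, 0, 20)
    dd <- f(tmin, tmax, 7.2, 31.1)
    expect_true(all(dd >= 0 & dd <= 31.1 - 7.2))
    expect_true(all(f(tmin + 1, tmax + 1, 7.2, 31.1) >= dd))
    expect_true(all(f(tmin, tmax + 1, 7.2, 31.1) >= dd))
  }
})

test_that("methods coincide when the day stays inside the thresholds", {
  set.seed(11)
  tmin <- runif(100, 8, 20)
  tmax <- tmin + runif(100, 0, 31 - 20)
  expect_equal(dd_single_triangle(tmin, tmax, 7.2, 31.1),
               dd_simple_average(tmin, tmax, 7.2, 31.1),
               tolerance = 1e-12)
})

test_that("missing and inverted temperatures are handled safely", {
  expect_true(is.na(dd_single_triangle(NA, 20, 10, 30)))
  expect_true(is.na(dd_simple_average(10, NA, 10, 30)))
  expect_warning(got <- dd_single_triangle(30, 10, 20, 40), "swapped")
  expect_equal(got, 2.5)
  expect_error(dd_simple_average(10, 20, 30, 20))  # ldt >= udt
})

test_that("per-stage table uses each stage's own thresholds", {
  ep <- ep_params()
  tab <- daily_stage_dd(12.2, 22.2, ep)
  expect_equal(dim(tab), c(1L, 4L))
  expect_equal(unname(tab[1, ]), rep(tab[[1, "egg"]], 4))  # common thresholds
  expect_equal(unname(daily_stage_dd(5, 7, ep)[1, ]), rep(0, 4))

  mixed <- ep
  mixed$stage_ldt[["egg"]] <- 5
  mixed$stage_ldt[["larva"]] <- 10
  tab2 <- daily_stage_dd(8, 8, mixed)
  expect_equal(tab2[[1, "egg"]], 3)
  expect_equal(tab2[[1, "larva"]], 0)

  bad <- ep; bad$calctype <- "sine"
  expect_error(daily_stage_dd(10, 20, bad), "unknown degree-day")
})
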