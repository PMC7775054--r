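test_that("seven cohorts discretize the emergence window at bin midpoints", {
  co <- make_cohorts(ep_params(), 7)
  expect_equal(co$emergence_dd,
               100 + (220 / 7) * (1:7 - 0.5), tolerance = 1e-12)
  expect_equal(sum(co$weight), 1, tolerance = 1e-9)
  # symmetric configuration: palindromic weights, middle cohort at the mean
  expect_equal(co$weight, rev(co$weight), tolerance = 1e-12)
  expect_equal(co$emergence_dd[middle_cohort(co)], 210)
})

test_that("cohort weights equal truncated-normal bin masses (oracle)", {
  for (p in list(ep_params(), ne_params())) {
    co <- make_cohorts(p, 7)
    dens <- function(x) stats::dnorm(x, p$distro_mean, sqrt(p$distro_var))
    edges <- seq(p$xdist1, p$xdist2, length.out = 8)
    oracle <- vapply(1:7, function(i)
      bin_mass_oracle(dens, edges[i], edges[i + 1], p$xdist1, p$xdist2),
      numeric(1))
    expect_equal(co$weight, oracle, tolerance = 1e-8)
  }
  # truncation clips the left tail for the tomato borer: asymmetric weights
  ne <- make_cohorts(ne_params(), 7)
  expect_gt(max(abs(ne$weight - rev(ne$weight))), 0.01)
})

test_that("single cohort and degenerate distributions behave as specified", {
  p <- ep_params()
  one <- make_cohorts(p, 1)
  expect_equal(one$emergence_dd, 210)
  expect_equal(one$weight, 1)

  p0 <- p; p0$distro_var <- 0
  expect_equal(make_cohorts(p0, 1)$weight, 1)
  expect_error(make_cohorts(p0, 3), "degenerate")
  expect_error(make_cohorts(p, 0), "positive integer")
})

test_that("weights sum to 1 for any n, shape, and bounds", {
  p <- ep_params()
  for (n in c(2, 5, 7, 20, 101)) {
    expect_equal(sum(make_cohorts(p, n)$weight), 1, tolerance = 1e-9)
  }
  pl <- p; pl$distro_shape <- "lognormal"
  for (n in c(3, 7, 50)) {
    col <- make_cohorts(pl, n)
    expect_equal(sum(col$weight), 1, tolerance = 1e-9)
    expect_true(all(col$weight > 0))
  }
})

test_that("weighted emergence mean converges to the truncated mean", {
  for (p in list(ep_params(), ne_params())) {
    dens <- function(x) stats::dnorm(x, p$distro_mean, sqrt(p$distro_var))
    target <- truncated_mean_oracle(dens, p$xdist1, p$xdist2)
    co <- make_cohorts(p, 101)
    expect_lt(abs(sum(co$emergence_dd * co$weight) - target), 0.5)
  }
})

test_that("lognormal parameterization matches its moment definition", {
  p <- ep_params()
  p$distro_shape <- "lognormal"
  cdf <- emergence_cdf(p)
  # the shifted variate has the stated mean: median of heavy grid check
  m <- p$distro_mean - p$xdist1
  v <- p$distro_var
  sigma2 <- log(1 + v / m^2)
  mu <- log(m) - sigma2 / 2
  expect_equal(exp(mu + sigma2 / 2), m)                    # mean
  expect_equal((exp(sigma2) - 1) * exp(2 * mu + sigma2), v) # variance
  expect_equal(cdf(p$xdist1), 0)

  bad <- p; bad$distro_mean <- bad$xdist1
  expect_error(make_cohorts(bad, 3), "distro_mean > xdist1")
})
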