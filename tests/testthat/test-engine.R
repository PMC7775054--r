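test_that("stage cycle starts after the overwintering stage", {
  expect_equal(stage_cycle(ep_params()),
               c("overwintering", "pupa", "adult", "egg", "larva"))
  expect_equal(stage_cycle(ne_params()),
               c("overwintering", "egg", "larva", "pupa", "adult"))
  egg_ow <- ep_params(); egg_ow$ow_stage <- "egg"
  expect_equal(stage_cycle(egg_ow),
               c("overwintering", "larva", "pupa", "adult", "egg"))
})

test_that("day-by-day advancement reproduces the hand simulation", {
  p <- ep_params()
  dd10 <- daily_stage_dd(12.2, 22.2, p)[1, ]  # 10 DDC/day at 7.2/31.1
  expect_equal(unname(dd10), rep(10, 4))

  st <- new_pheno_state(p)
  expect_equal(st$stage, "overwintering")
  days <- integer(0)
  for (d in 1:60) {
    st <- advance_day(st, dd10, p, cohort_ow_dd = 210, day = d)
    days <- c(days, d)
  }
  # overwintering larva completes day 21, pupa (128) day 34 with 2 DDC
  # carryover, adult (71) day 41 -> oviposition, generation 1
  expect_equal(st$event_day["g0", "ow"], 21L)
  expect_equal(st$event_day["g0", "pupa"], 34L)   # event = full pupal duration
  expect_equal(st$event_day["g1", "egg"], 54L)    # 1 + 10 (n - 41) >= 126
  expect_equal(st$generation, 1L)
  expect_equal(st$cum_dd, 600)

  # zero degree-days leave everything unchanged
  frozen <- advance_day(st, c(egg = 0, larva = 0, pupa = 0, adult = 0),
                        p, 210, day = 61)
  expect_equal(frozen$stage_dd_accum, st$stage_dd_accum)
  expect_equal(frozen$generation, st$generation)
  expect_equal(frozen$event_day, st$event_day)

  # missing weather freezes the state and counts the day
  na_day <- advance_day(st, c(egg = NA, larva = NA, pupa = NA, adult = NA),
                        p, 210, day = 61)
  expect_equal(na_day$stage_dd_accum, st$stage_dd_accum)
  expect_equal(na_day$missing_days, st$missing_days + 1L)
})

test_that("constant-temperature runs hit the derived voltinism values", {
  p <- ep_params()
  expect_equal(voltinism(run_cohort(const_weather(17.2), p, 210)), 5L)
  expect_equal(voltinism(run_cohort(const_weather(7.2), p, 210)), 0L)
  # 25 C: 17.8 DDC/day; first oviposition day 23, then every ~41.2 days,
  # so the 9th and last oviposition lands near day 353
  expect_equal(voltinism(run_cohort(const_weather(25), p, 210)), 9L)

  tr <- run_cohort(const_weather(17.2), p, 210)
  expect_equal(tr$event_day["g1", "egg"], 54L)

  # overwintering adult moves straight to eggs, incrementing the generation
  ne <- ne_params()
  tr2 <- run_cohort(const_weather(30, days = 20), ne, 50)
  expect_equal(tr2$event_day["g0", "ow"], 3L)  # 21.11 DDC/day, 50 DDC needed
  expect_equal(tr2$stage[3], "egg")
  expect_equal(tr2$generation[3], 1L)
})

test_that("voltinism matches the constant-temperature closed form", {
  p <- ep_params()
  G <- sum(p$stage_dd)            # 734 DDC per full generation
  ow <- 210
  d_first <- ow + p$stage_dd[["pupa"]] + p$stage_dd[["adult"]]
  for (temp in c(12, 15, 17.2, 20, 23, 26, 29)) {
    d <- temp - 7.2
    closed <- max(0, 1 + floor((365 * d - d_first) / G))
    if (365 * d < d_first) closed <- 0
    expect_equal(voltinism(run_cohort(const_weather(temp), p, ow)),
                 as.integer(closed), info = paste("temp", temp))
  }
})

test_that("event days never decrease with generation or emergence demand", {
  p <- ep_params()
  w <- const_weather(17.2)
  tr <- run_cohort(w, p, 210)
  for (s in colnames(tr$event_day)) {
    dvec <- tr$event_day[, s]
    dvec <- dvec[!is.na(dvec)]
    expect_true(!is.unsorted(dvec), info = s)
  }
  # a cohort that needs more overwintering DD is late everywhere
  tr_hi <- run_cohort(w, p, 304.3)
  lo <- tr$event_day; hi <- tr_hi$event_day
  both <- !is.na(lo) & !is.na(hi)
  expect_true(all(hi[both] >= lo[both]))
})

test_that("cohort combination weights composition and event summaries", {
  p <- ep_params()
  co <- make_cohorts(p, 7)
  w <- const_weather(17.2)
  trs <- lapply(co$emergence_dd, function(e) run_cohort(w, p, e))
  ps <- combine_cohorts(trs, co)

  # per-day fractions sum to one
  for (d in unique(ps$composition$sample_day)) {
    expect_equal(sum(ps$composition$fraction[ps$composition$sample_day == d]),
                 1, tolerance = 1e-9)
  }
  # early-emerging cohorts pull the earliest date ahead of the average
  e1 <- ps$events[ps$events$generation == 1 & ps$events$stage == "egg", ]
  expect_lt(e1$earliest, e1$average)

  # degenerate cohort set: identical trajectories collapse the summary
  co1 <- make_cohorts(p, 1)
  ps1 <- combine_cohorts(list(run_cohort(w, p, co1$emergence_dd)), co1)
  expect_true(all(ps1$composition$fraction == 1))
  expect_equal(ps1$events$earliest, ps1$events$average)

  # two cohorts, equal weights: plain average of event days
  ow2 <- c(100, 320)
  tr2 <- lapply(ow2, function(e) run_cohort(w, p, e))
  co2 <- structure(data.frame(emergence_dd = ow2, weight = c(0.5, 0.5)),
                   class = c("cohort_set", "data.frame"))
  ev2 <- combine_cohorts(tr2, co2)$events
  ow_row <- ev2[ev2$stage == "ow", ]
  d1 <- tr2[[1]]$event_day["g0", "ow"]
  d2 <- tr2[[2]]$event_day["g0", "ow"]
  expect_equal(ow_row$earliest, min(d1, d2))
  expect_equal(ow_row$average, round((d1 + d2) / 2))

  expect_error(combine_cohorts(trs[1:2], co))  # one trajectory per cohort
  short <- run_cohort(w, p, 210, sample_every = 30)
  expect_error(combine_cohorts(c(trs[-7], list(short)), co),
               "mismatched sampling")
})

test_that("weather input validation catches gaps and sampling typos", {
  p <- ep_params()
  w <- const_weather(17.2, days = 30)
  broken <- w[-10, ]
  expect_error(run_cohort(broken, p, 210), "consecutive")
  expect_error(run_cohort(w, p, 210, sample_every = 3), "sample_every")
  expect_silent(run_cohort(w, p, 210, sample_every = 14))
})
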