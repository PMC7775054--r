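test_that("shipped parameter files load with their published values", {
  ep <- ep_params()
  expect_equal(ep$stage_ldt[["egg"]], 7.2)
  expect_equal(ep$stage_udt[["adult"]], 31.1)
  expect_equal(unname(ep$stage_dd), c(127, 408, 128, 71))
  expect_equal(ep$ow_stage, "larva")
  expect_equal(ep$coldstress_units_max2, 1125)
  expect_equal(ep$heatstress_units_max1, 375)
  expect_equal(ep$event_dd[["egg"]], 126)
  expect_equal(ep$distro_mean, 210)
  expect_equal(ep$calctype, "triangle")

  ne <- ne_params()
  expect_equal(unname(ne$stage_ldt), rep(8.89, 4))
  expect_equal(ne$stage_dd[["pupa"]], 203)
  expect_equal(ne$ow_stage, "adult")
  expect_equal(ne$heatstress_threshold, 32)
  expect_equal(ne$xdist1, 0)
  expect_equal(ne$xdist2, 111)
})

test_that("missing keys and invariant violations are clear errors", {
  src <- readLines(system.file("extdata", "epiphyas_postvittana.txt",
                               package = "phenorisk"))
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines(src[!grepl("^eggDD:", src)], f)
  expect_error(load_params(f), "eggDD")

  bad <- sub("^coldstress_units_max1: 875", "coldstress_units_max1: 1200", src)
  bad <- sub("^coldstress_units_max2: 1125", "coldstress_units_max2: 1100", bad)
  writeLines(bad, f)
  expect_error(load_params(f), "coldstress_units_max1 < coldstress_units_max2")

  bad <- sub("^eggLDT: 7.2", "eggLDT: 35", src)
  writeLines(bad, f)
  expect_error(load_params(f), "stage_ldt < stage_udt")

  bad <- sub("^eggEventDD: 126", "eggEventDD: 500", src)
  writeLines(bad, f)
  expect_error(load_params(f), "event_dd")

  expect_error(load_params(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("Fahrenheit thresholds are rounded to integer F before conversion", {
  mk <- function(units, ldt) species_params(
    name = "synthetic", units = units,
    stage_ldt = rep(ldt, 4), stage_udt = rep(if (units == "F") 88 else 31.1, 4),
    stage_dd = c(127, 408, 128, 71), ow_stage = "larva",
    event_dd = c(0, 0, 0, 0),
    coldstress_threshold = if (units == "F") 37.4 else 3,
    coldstress_units_max1 = 875, coldstress_units_max2 = 1125,
    heatstress_threshold = if (units == "F") 87.8 else 31,
    heatstress_units_max1 = 375, heatstress_units_max2 = 550,
    distro_mean = 210, distro_var = 2500, xdist1 = 100, xdist2 = 320)

  # 44.96 F rounds to 45 F = 7.222 C; the .96 is discarded by rounding
  pf <- mk("F", 44.96)
  expect_equal(unname(pf$stage_ldt), rep((45 - 32) * 5 / 9, 4))
  expect_equal(unname(pf$stage_udt), rep((88 - 32) * 5 / 9, 4))
  expect_equal(pf$coldstress_threshold, (37 - 32) * 5 / 9)
  # degree-day quantities scale by 5/9 without offset
  expect_equal(unname(pf$stage_dd), c(127, 408, 128, 71) * 5 / 9)

  # Celsius values are taken as-is, no rounding
  pc <- mk("C", 7.15)
  expect_equal(pc$stage_ldt[["egg"]], 7.15)
})

test_that("stage name synonyms normalize and unknown stages fail", {
  expect_equal(ep_params()$ow_stage, "larva")  # file says "larvae"
  expect_error(phenorisk:::.normalize_stage("nymphs"), "unknown life stage")
})
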