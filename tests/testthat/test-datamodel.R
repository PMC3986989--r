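# Domain types, packaged fixtures and sample-table validation.

test_that("packaged parameter fixtures carry the published values", {
  b1 <- default_backgrounds("Site1")
  expect_equal(unname(unclass(b1)[metal_ids()]),
               c(0.107, 57.5, 23, 29.3, 16.8, 67.9))
  expect_identical(attr(b1, "provenance"), "site_local")
  b2 <- default_backgrounds("Site2")
  expect_equal(b2[["Cd"]], 0.092)
  expect_equal(b2[["Pb"]], 25.1)
  expect_error(default_backgrounds("Site3"), "Site1, Site2")

  expect_equal(default_toxicity_factors(),
               c(Cd = 30, Cr = 2, Cu = 5, Ni = 5, Pb = 5, Zn = 1))

  p <- default_exposure_params()
  expect_equal(p$child$BW, 16.2)
  expect_equal(p$adult$SA, 5700)
  expect_equal(p$shared$PEF, 1.36e9)
  expect_equal(averaging_time(p, "child", "nc"), 2190)
  expect_equal(averaging_time(p, "adult", "nc"), 10950)
  expect_equal(averaging_time(p, type = "ca"), 26280)

  tox <- default_tox_params()
  expect_equal(tox$RfD_ing[tox$metal == "Zn"], 0.3)
  # unavailable routes are NA, not zero: RfC exists only for Cd and Ni
  expect_identical(tox$metal[!is.na(tox$RfC_inh)], c("Cd", "Ni"))
  expect_identical(tox$metal[!is.na(tox$CSF_ing)], "Pb")
})

test_that("Grade I screening values exceed both sites' backgrounds", {
  scr <- grade1_screening_values()
  for (site in c("Site1", "Site2")) {
    b <- default_backgrounds(site)
    expect_true(all(scr[metal_ids()] > unclass(b)[metal_ids()]))
  }
})

test_that("background_set validates coverage and positivity", {
  expect_error(background_set(c(Cd = 1, Cr = 1)), "missing metal")
  full <- setNames(rep(1, 6), metal_ids())
  expect_error(background_set(replace(full, 2, 0)), "> 0")
  bs <- background_set(full, "average_shale")
  expect_identical(attr(bs, "provenance"), "average_shale")
})

test_that("load_samples round-trips a well-formed design table", {
  tbl <- generate_transects(seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples(tbl, f)
  back <- load_samples(f)
  expect_equal(nrow(back), 42)
  expect_equal(back$zone, tbl$zone)
  expect_equal(back$Cd, tbl$Cd, tolerance = 1e-12)
})

test_that("sample validation rejects bad rows with row numbers", {
  tbl <- as.data.frame(generate_transects(seed = 7))

  bad <- tbl
  bad$Cd[5] <- -0.1
  expect_error(as_sample_table(bad), "Row\\(s\\) 5.*Cd")

  bad <- tbl
  bad$zone[3] <- "ditch"
  expect_error(as_sample_table(bad), "Row\\(s\\) 3.*trench, working, piling")

  bad <- tbl[, setdiff(names(tbl), "Ni")]
  expect_error(as_sample_table(bad), "missing metal column\\(s\\): Ni")

  bad <- tbl
  bad$distance_m[2] <- 35
  expect_error(as_sample_table(bad), "Row\\(s\\) 2.*distance_m")

  bad <- tbl
  bad[2, c("site", "transect", "zone", "distance_m")] <-
    bad[1, c("site", "transect", "zone", "distance_m")]
  expect_error(as_sample_table(bad), "Duplicate")
})

test_that("compass side labels normalise to side-agnostic zones", {
  expect_identical(normalize_zone(c("E20", "W20", "N50", "s50")),
                   c("d20_side1", "d20_side2", "d50_side1", "d50_side2"))
  expect_identical(zone_distance(c("trench", "working", "piling",
                                   "d20_side1", "d50_side2")),
                   c(0, 10, 10, 20, 50))
  expect_error(normalize_zone("ditch"), "Allowed labels")
})

test_that("config round-trip reproduces every parameter exactly", {
  params <- default_parameters("Site1")
  f <- withr::local_tempfile(fileext = ".cfg")
  write_params_config(params, f)
  back <- read_params_config(f)

  expect_identical(unname(unclass(back$backgrounds)[metal_ids()]),
                   unname(unclass(params$backgrounds)[metal_ids()]))
  expect_identical(back$toxicity, params$toxicity)
  expect_identical(back$exposure$child, params$exposure$child)
  expect_identical(back$exposure$adult, params$exposure$adult)
  expect_identical(back$exposure$shared, params$exposure$shared)
  expect_identical(back$tox, params$tox)
})

test_that("config overrides merge over fixtures", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("[backgrounds.Site1]", "Pb = 20",
               "[exposure.child]", "BW = 15",
               "[tox.Zn]", "RfD_ing = 0.2"), f)
  p <- read_params_config(f)
  expect_equal(p$backgrounds[["Pb"]], 20)
  expect_equal(p$backgrounds[["Cd"]], 0.107)  # untouched fixture value
  expect_equal(p$exposure$child$BW, 15)
  expect_equal(p$exposure$adult$BW, 61.8)
  expect_equal(p$tox$RfD_ing[p$tox$metal == "Zn"], 0.2)
  expect_error(read_params_config(tempfile()), "not found")
})
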