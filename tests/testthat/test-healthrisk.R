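# Three-pathway doses, hazard quotients/index, age-adjusted factors and
# carcinogenic risk.

test_that("unit doses match the factor-chain oracle and frozen values", {
  expect_equal(cdi_ingestion_nc(0, "child"), 0)
  expect_equal(cdi_ingestion_nc(1, "child"), 1.183832e-05, tolerance = 1e-6)
  expect_equal(cdi_ingestion_nc(1, "adult"), 1.551625e-06, tolerance = 1e-6)
  expect_equal(ec_inhalation_nc(1, "child"), 7.050766e-10, tolerance = 1e-6)
  expect_equal(cdi_dermal_nc(1, "child"), 9.944191e-07, tolerance = 1e-6)
  expect_equal(cdi_dermal_nc(1, "adult"), 6.190983e-09, tolerance = 1e-6)

  # round-the-clock exposure time makes inhalation receptor-independent
  expect_equal(ec_inhalation_nc(3.7, "child"), ec_inhalation_nc(3.7, "adult"),
               tolerance = 1e-14)

  set.seed(31)
  for (i in 1:20) {
    C <- stats::runif(1, 0, 400)
    for (r in c("child", "adult")) {
      expect_equal(cdi_ingestion_nc(C, r), oracle_cdi_ing(C, r),
                   tolerance = 1e-14)
      expect_equal(ec_inhalation_nc(C, r), oracle_ec_inh(C, r),
                   tolerance = 1e-14)
      expect_equal(cdi_dermal_nc(C, r), oracle_cdi_dermal(C, r),
                   tolerance = 1e-14)
    }
  }
})

test_that("age-adjusted exposure factors reproduce the published values", {
  expect_equal(age_adjusted_ingestion(), 112.90903, tolerance = 1e-7)
  expect_equal(signif(age_adjusted_ingestion(), 3), 113)
  expect_equal(age_adjusted_dermal(), 362.3589, tolerance = 1e-6)
  expect_equal(signif(age_adjusted_dermal(), 4), 362.4)
  expect_equal(dermal_abs_factor(), 6.377174, tolerance = 1e-6)

  # child-only span: adult term vanishes when ED_adult = ED_child
  p <- default_exposure_params()
  p$adult$ED <- p$child$ED
  expect_equal(age_adjusted_ingestion(p), 6 * 200 / 16.2, tolerance = 1e-12)
  expect_equal(age_adjusted_dermal(p), 6 * 2800 * 0.2 / 16.2,
               tolerance = 1e-12)
  p2 <- default_exposure_params()
  p2$child$IngR <- 0; p2$adult$IngR <- 0
  expect_equal(age_adjusted_ingestion(p2), 0)
  p3 <- default_exposure_params()
  p3$child$AF <- 0; p3$adult$AF <- 0
  expect_equal(age_adjusted_dermal(p3), 0)
})

test_that("hazard index sums evaluable routes and skips missing ones", {
  expect_equal(hazard_index(setNames(rep(0, 6), metal_ids()), "child")$HI, 0)

  hz <- hazard_index(c(Zn = 300), "child")
  hq <- hz$HQ
  expect_equal(hq$HQ[hq$route == "ing"], 300 * 1.183832e-05 / 0.3,
               tolerance = 1e-6)
  expect_equal(hq$HQ[hq$route == "dermal"], 300 * 9.944191e-07 / 0.3,
               tolerance = 1e-6)
  # Zn has no inhalation reference concentration
  expect_identical(hz$skipped$route, "inh")
  expect_equal(hz$HI, sum(hq$HQ))

  expect_equal(hazard_index(c(Zn = 300), "child")$HI,
               oracle_hi(c(Zn = 300), "child"), tolerance = 1e-12)

  # nothing evaluable at all is an error, not a silent zero
  tox0 <- default_tox_params()
  tox0$RfD_ing <- NA_real_
  tox0$RfC_inh <- NA_real_
  expect_error(hazard_index(c(Zn = 1), "child", tox = tox0), "evaluable")
})

test_that("children carry a higher hazard index than adults", {
  set.seed(41)
  for (i in 1:30) {
    conc <- setNames(stats::runif(6, 0, 300), metal_ids())
    hi_c <- hazard_index(conc, "child")$HI
    hi_a <- hazard_index(conc, "adult")$HI
    expect_gt(hi_c, hi_a)
    expect_equal(hi_c, oracle_hi(conc, "child"), tolerance = 1e-12)
    expect_equal(hi_a, oracle_hi(conc, "adult"), tolerance = 1e-12)
  }
})

test_that("cancer risk evaluates the documented routes per carcinogen", {
  expect_equal(cancer_risk(setNames(rep(0, 6), metal_ids()))$total_risk, 0)

  cr <- cancer_risk(c(Pb = 1))
  expect_equal(cr$risk$risk[cr$risk$route == "ing"], 1.278169e-08,
               tolerance = 1e-6)
  cd <- cancer_risk(c(Cd = 1))
  expect_equal(cd$risk$risk[cd$risk$route == "inh"], 5.288074e-10,
               tolerance = 1e-6)
  # Cd has no oral slope factor: ingestion and dermal are skipped
  expect_setequal(cd$skipped$route, c("ing", "dermal"))

  # non-carcinogens are ignored entirely
  zn <- cancer_risk(c(Zn = 100, Cu = 100))
  expect_equal(zn$total_risk, 0)
  expect_equal(nrow(zn$risk), 0)

  set.seed(51)
  for (i in 1:20) {
    conc <- setNames(stats::runif(6, 0, 100), metal_ids())
    expect_equal(cancer_risk(conc)$total_risk, oracle_total_risk(conc),
                 tolerance = 1e-12)
  }

  # linearity in concentration
  conc <- c(Pb = 20, Cd = 0.2, Cr = 60, Ni = 30)
  expect_equal(cancer_risk(2 * conc)$total_risk,
               2 * cancer_risk(conc)$total_risk, tolerance = 1e-12)

  # dermal absorption placement options bracket the default
  within <- cancer_risk(c(Pb = 10))$total_risk
  child <- cancer_risk(c(Pb = 10), dermal_abs = "child")$total_risk
  adult <- cancer_risk(c(Pb = 10), dermal_abs = "adult")$total_risk
  expect_gt(child, within)
  expect_lt(adult, within)
})

test_that("zone health profile is flat at background and one row per zone", {
  flat <- make_flat_table()
  prof <- health_profile(flat)
  expect_equal(nrow(prof), 7)
  expect_equal(diff(range(prof$HI_child)), 0, tolerance = 1e-12)
  expect_equal(diff(range(prof$total_risk)), 0, tolerance = 1e-12)
  expect_true(all(prof$HI_child > prof$HI_adult))

  single <- prof <- health_profile(make_flat_table(transects = 1)[1, ])
  expect_equal(nrow(single), 1)
})
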