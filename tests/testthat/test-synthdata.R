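# Synthetic transect generator and enrichment-recovery harness.

test_that("default design yields 2 sites x 3 transects x 7 zones", {
  s <- generate_transects(seed = 42)
  expect_equal(nrow(s), 42)
  expect_equal(sort(unique(s$site)), c("Site1", "Site2"))
  expect_equal(length(unique(s$transect)), 3)
  expect_equal(sort(unique(s$zone)), sort(zone_levels()$zone))
  expect_true(all(s[, metal_ids()] > 0))
})

test_that("the same seed reproduces a byte-identical CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(generate_transects(seed = 123), f1)
  write_samples(generate_transects(seed = 123), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_samples(generate_transects(seed = 124), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("deterministic limit reproduces B * exp(lambda * s) exactly", {
  cfg <- generator_config(gamma = 0, nu = 0, sigma = 1e-12)
  s <- generate_transects(cfg, seed = 1)
  b1 <- default_backgrounds("Site1")
  trench_cd <- s$Cd[s$site == "Site1" & s$zone == "trench"]
  expect_equal(trench_cd, rep(b1[["Cd"]] * exp(1), 3), tolerance = 1e-6)
  # Zn has zero enrichment everywhere
  expect_equal(s$Zn[s$site == "Site1"],
               rep(b1[["Zn"]], 21), tolerance = 1e-6)
})

test_that("config validation rejects malformed schedules and scales", {
  expect_error(generator_config(schedule = c(trench = 1)), "missing zone")
  expect_error(generator_config(lambda = c(Cd = 1)), "missing metal")
  expect_error(generator_config(sigma = 0), "sigma")
  sched <- generator_config()$schedule
  sched[["trench"]] <- -1
  expect_error(generator_config(schedule = sched), ">= 0")
})

test_that("expected concentrations decrease with distance for enriched metals", {
  # average many seeds: zone band means must order trench > working > piling
  # > 20 m > 50 m for every metal with positive enrichment scale
  cfg <- generator_config()
  acc <- 0
  for (seed in 1:30) {
    s <- generate_transects(cfg, seed = seed)
    zm <- dplyr::summarise(dplyr::group_by(s, zone),
                           dplyr::across(dplyr::all_of(metal_ids()), mean),
                           .groups = "drop")
    acc <- acc + as.matrix(zm[match(c("trench", "working", "piling",
                                      "d20_side1", "d50_side1"), zm$zone),
                              metal_ids()])
  }
  for (m in c("Cd", "Cu", "Ni", "Pb")) {
    expect_true(all(diff(acc[, m]) < 0))
  }
})

test_that("log concentrations look lognormal and carry the source structure", {
  # marginal lognormality, judged across seeds at a fixed design cell (within
  # one table the transect-level factor makes pooled residuals multimodal)
  cell <- vapply(1:60, function(seed) {
    s <- generate_transects(seed = seed + 300)
    log(s$Cd[s$site == "Site1" & s$transect == "T1" & s$zone == "trench"])
  }, numeric(1))
  expect_gt(stats::shapiro.test(cell)$p.value, 0.01)

  # the unenriched, factor-free metal is plain lognormal within a site:
  # Shapiro rejection rate across seeds stays near the nominal 5% level
  rej <- vapply(1:40, function(seed) {
    s <- generate_transects(seed = seed + 500)
    stats::shapiro.test(log(s$Zn[s$site == "Site1"]))$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)

  # within-group correlations exceed cross-group correlations on average
  s <- generate_transects(seed = 77)
  cors <- cor(log(as.matrix(s[, metal_ids()])))
  anthro <- c("Cd", "Cu", "Ni", "Pb")
  within_a <- cors[anthro, anthro][upper.tri(diag(4))]
  within_m <- cors["Cr", "Zn"]
  cross <- cors[anthro, c("Cr", "Zn")]
  expect_gt(mean(within_a), mean(cross))
  expect_gt(within_m, mean(cross))
})

test_that("enrichment estimator recovers the generator truth", {
  cfg <- generator_config()

  # noise-free limit: estimates equal lambda * s(zone) to numerical precision
  cfg0 <- generator_config(gamma = 0, nu = 0, sigma = 1e-12)
  est0 <- estimate_enrichment(generate_transects(cfg0, seed = 2),
                              cfg0$backgrounds)
  truth0 <- cfg0$lambda[est0$metal] * cfg0$schedule[est0$zone]
  expect_equal(est0$estimate, unname(truth0), tolerance = 1e-6)

  # background-only data: estimates all near zero
  estb <- estimate_enrichment(make_flat_table(), default_backgrounds("Site1"))
  expect_equal(estb$estimate, rep(0, nrow(estb)), tolerance = 1e-12)

  # default noise: estimates land within normal-theory bounds of the truth
  cfg200 <- generator_config(transects_per_site = 100)
  s200 <- generate_transects(cfg200, seed = 3)
  est <- estimate_enrichment(s200, cfg200$backgrounds)
  truth <- cfg200$lambda[est$metal] * cfg200$schedule[est$zone]
  sd_m <- ifelse(est$metal %in% cfg200$anthro_metals,
                 sqrt(cfg200$sigma^2 + cfg200$gamma^2),
                 ifelse(est$metal %in% cfg200$mixed_metals,
                        sqrt(cfg200$sigma^2 + cfg200$nu^2), cfg200$sigma))
  ok <- abs(est$estimate - truth) <= 3 * sd_m / sqrt(est$n)
  expect_gte(mean(ok), 0.95)
})
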