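test_that("per-field rate inverts the concentration formula", {
  cfg <- simulation_config(1e7, default_prep())
  # C * p_TS * a / A = 1e7 * 0.02 * 1e-4 / 222
  expect_equal(fibers_per_field_rate(cfg), 1e7 * 0.02 * 1e-4 / 222)
  expect_equal(round(fibers_per_field_rate(cfg), 4), 0.0901)
  expect_equal(fibers_per_field_rate(
    simulation_config(0, default_prep())), 0)

  # round trip: lambda * N_fields fibers recover the truth exactly
  lambda <- fibers_per_field_rate(cfg)
  n_fields <- 1000
  expect_equal(lambda * n_fields *
                 analytical_sensitivity(default_prep(), n_fields), 1e7)
})

test_that("sessions honour the stop rules", {
  # zero truth: every planned field examined, nothing found
  s0 <- simulate_session(simulation_config(0, default_prep(), seed = 1))
  expect_identical(s0$n_fields_examined, 1110L)
  expect_identical(nrow(s0$fibers), 0L)
  expect_identical(s0$stop_reason, "area_target_reached")

  # huge truth: cap reached almost immediately, n_f >= cap
  sbig <- simulate_session(simulation_config(5e9, default_prep(), seed = 2))
  expect_identical(sbig$stop_reason, "fiber_cap_reached")
  expect_gte(countable_fibers(sbig), 50)
  expect_lt(sbig$n_fields_examined, 1110L)

  # moderate truth, generous cap: area target reached
  smod <- simulate_session(simulation_config(2e6, default_prep(),
                                             fiber_cap = Inf, seed = 3))
  expect_identical(smod$stop_reason, "area_target_reached")
  expect_identical(smod$n_fields_examined, 1110L)
})

test_that("seeded simulation is bit-reproducible", {
  cfg <- simulation_config(49e6, default_prep(), seed = 42)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1, s2)
  c1 <- simulate_campaign(cfg, 4)
  c2 <- simulate_campaign(cfg, 4)
  expect_identical(c1, c2)
  # replicates within one campaign are not copies of each other
  expect_false(identical(c1[[1]]$n_counted, c1[[2]]$n_counted) &&
                 identical(c1[[1]]$session$fibers, c1[[2]]$session$fibers))
})

test_that("generated fibers pass the counting rule unless sub-um is asked for", {
  s <- simulate_session(simulation_config(30e6, default_prep(), seed = 5))
  expect_true(all(s$fibers$length_um > 1))
  expect_identical(countable_fibers(s), nrow(s$fibers))

  cfg <- simulation_config(30e6, default_prep(), sub_um_fraction = 0.5,
                           seed = 6)
  s2 <- simulate_session(cfg)
  expect_gt(sum(s2$fibers$length_um < 1), 0)
  expect_identical(countable_fibers(s2),
                   sum(s2$fibers$length_um > 1))
  expect_true(all(s2$fibers$length_um >= s2$fibers$width_um))
})

test_that("pure Poisson fields have unit index of dispersion", {
  set.seed(81)
  # lambda ~ 0.5 over 50-field sessions, pooled across many sessions
  prep <- default_prep()
  target <- analytical_sensitivity(prep, 50)
  truth <- 0.5 / (tissue_mass_on_filter(prep) * prep$field_area_mm2 /
                    prep$active_area_mm2)
  counts <- unlist(lapply(1:10000, function(i) {
    s <- fiberburden:::simulate_session_impl(
      simulation_config(truth, prep, target_as = target))
    tabulate(s$fibers$field_index + 1L, nbins = s$n_fields_examined)
  }))
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.03)
})

test_that("overdispersion inflates the per-field variance as specified", {
  set.seed(82)
  d <- 2
  lambda <- 1.5
  k <- fiberburden:::draw_field_counts(2e5, lambda, d)
  expect_equal(mean(k), lambda, tolerance = 0.03)
  expect_equal(var(k), lambda * (1 + d * lambda), tolerance = 0.06)
})

test_that("the estimator recovers the truth over uncapped campaigns", {
  truth <- 2e6  # expected 20 fibers per session, cap far away
  cfg <- simulation_config(truth, default_prep(), seed = 83)
  fits <- simulate_campaign(cfg, 1000)
  est <- vapply(fits, function(f) f$concentration, numeric(1))
  n_bar <- truth / 1e5  # expected countable fibers per session
  mc_se <- truth / sqrt(n_bar) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * mc_se)
  # empirical SD within 10% of the Poisson prediction C/sqrt(E n)
  expect_gt(sd(est) / (truth / sqrt(n_bar)), 0.9)
  expect_lt(sd(est) / (truth / sqrt(n_bar)), 1.1)
  expect_true(all(vapply(fits, function(f)
    f$stop_reason == "area_target_reached", logical(1))))
})

test_that("with the cap binding the estimator bias stays small", {
  # lambda = 5 per field: the 50-fiber cap is hit in ~10 fields; completing
  # the field leaves only a small upward ratio bias
  prep <- default_prep()
  lam <- 5
  truth <- lam * prep$active_area_mm2 /
    (tissue_mass_on_filter(prep) * prep$field_area_mm2)
  cfg <- simulation_config(truth, prep,
                           target_as = analytical_sensitivity(prep, 500),
                           seed = 84)
  set.seed(84)
  blk <- fiberburden:::sim_counts_block(cfg, 10000)
  expect_true(all(blk$capped))
  est <- blk$n_f * analytical_sensitivity(prep, 1) / blk$n_fields
  rel_bias <- (mean(est) - truth) / truth
  expect_lt(abs(rel_bias), 0.02)
})

test_that("coverage of the exact interval under and beyond the model", {
  prep <- default_prep()
  # expected 20 fibers per session; exact intervals are conservative
  cfg <- simulation_config(2e6, prep, seed = 85)
  cov95 <- coverage_experiment(cfg, 10000, level = 0.95)
  expect_gte(cov95, 0.945)
  expect_lte(cov95, 0.97)
  cov50 <- coverage_experiment(simulation_config(2e6, prep, seed = 86),
                               10000, level = 0.5)
  expect_gte(cov50, 0.5)
  # strong filter inhomogeneity breaks the nominal Poisson coverage; the
  # per-field variance lambda(1 + d*lambda) only bites at appreciable
  # per-field rates, so examine 20 fields at lambda = 1
  lam1_truth <- prep$active_area_mm2 /
    (tissue_mass_on_filter(prep) * prep$field_area_mm2)
  covod <- coverage_experiment(
    simulation_config(lam1_truth, prep, dispersion = 2,
                      target_as = analytical_sensitivity(prep, 20),
                      seed = 87), 10000)
  expect_lt(covod, 0.95)
  expect_error(coverage_experiment(cfg, 50),
               class = "fiberburden_invalid_input")
})

test_that("simulated sessions round-trip through the on-disk formats", {
  cfg <- simulation_config(49e6, default_prep(), seed = 88)
  s <- simulate_session(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  sj <- withr::local_tempfile(fileext = ".json")
  write_count_sheet(s$fibers, csv)
  write_session_json(s, sj)
  back <- read_session(csv, session_path = sj)
  f1 <- fiber_burden(s, cfg$prep)
  f2 <- fiber_burden(back, cfg$prep)
  expect_identical(f1$n_counted, f2$n_counted)
  expect_equal(f1$concentration, f2$concentration)
  expect_identical(f1$stop_reason, f2$stop_reason)
})

test_that("simulation configs load from JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "true_concentration": 49e6, "dispersion": 0, "fiber_cap": 50,
    "target_as": 1e5, "seed": 9,
    "prep": {"dry_mass_ashed_mg": 100, "suspension_volume_ml": 100,
             "filtered_volume_ml": 20, "active_area_mm2": 222,
             "field_area_mm2": 0.0001}
  }', path)
  cfg <- read_sim_config_json(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$true_concentration, 49e6)
  expect_identical(cfg$seed, 9L)
  expect_identical(simulate_session(cfg), simulate_session(cfg))
})
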