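test_that("generation is deterministic per seed and leaves global RNG alone", {
  w1 <- generate_foodweb(web_gen_spec(seed = 9))
  set.seed(123)
  probe_before <- runif(1)
  w2 <- generate_foodweb(web_gen_spec(seed = 9))
  expect_equal(w1, w2)
  # the generator must not disturb the caller's random stream
  set.seed(123)
  expect_equal(runif(1), probe_before)
  invisible(generate_foodweb(web_gen_spec(seed = 1)))
  expect_false(runif(1) == probe_before)
})

test_that("generated webs satisfy every structural invariant", {
  for (seed in 1:40) {
    spec <- web_gen_spec(n_groups = 8 + seed %% 5, n_producers = 2,
                         seed = seed)
    web <- generate_foodweb(spec)
    g <- web$groups
    cons <- g$group_class == "consumer"
    expect_true(all(abs(rowSums(web$diet)[cons] - 1) < 1e-9))
    expect_true(all(rowSums(web$diet)[!cons] == 0))
    expect_true(all(g$EE >= 0 & g$EE <= 0.95 + 1e-12))
    expect_true(all(g$QB[cons] >= g$PB[cons]))
    # back-solved EE balances the web exactly
    expect_lt(max(abs(mass_balance_residuals(web))), 1e-8)
    # constructed identity: consumption rows equal B * QB
    expect_equal(unname(rowSums(consumption_matrix(web))), g$B * g$QB,
                 tolerance = 1e-12)
  }
})

test_that("a three-group chain spec yields integer trophic levels", {
  spec <- web_gen_spec(n_groups = 3, n_producers = 1, n_detritus = 0,
                       connectance = 1e-9, seed = 2)
  web <- generate_foodweb(spec)
  expect_equal(unname(trophic_levels(web)), c(1, 2, 3))
})

test_that("the default 29-group web mirrors the named guild conventions", {
  web <- generate_foodweb(web_gen_spec())
  g <- web$groups
  expect_equal(nrow(g), 29)
  expect_equal(sum(g$group_class == "detritus"), 1)
  expect_setequal(g$name[g$direct_uptake],
                  c("phytoplankton_diatoms", "phytoplankton_flagellates",
                    "phytoplankton_picoplankton", "copepods", "euphausiids"))
  expect_equal(g$muscle_fraction[g$name == "cod"], 0.5)
  expect_equal(g$muscle_fraction[g$name == "shrimp"], 0.15)
  expect_equal(g$muscle_fraction[g$name == "bivalves"], 1)
  expect_true(all(c("herring", "cod", "shrimp") %in% g$name[g$commercial]))
  # the grazing crustaceans feed on phytoplankton only
  for (nm in c("copepods", "euphausiids")) {
    expect_equal(sum(web$diet[nm, 1:3]), 1)
  }
})

test_that("uptake calibration recovers the closed form and round-trips", {
  web <- single_producer_web(B = 3, PB = 10, area = 1, depth = 10)
  params <- calibrate_uptake(web, targets = 40, excretion = 0.1,
                             water_concentration = 2,
                             detritus_routing = FALSE)
  # single compartment: u = target * e / C_w
  expect_equal(unname(params$uptake), 40 * 0.1 / 2)

  p0 <- calibrate_uptake(web, targets = 0, excretion = 0.1)
  expect_equal(unname(p0$uptake), 0)

  for (seed in c(1, 2)) {
    web5 <- generate_foodweb(web_gen_spec(n_groups = 5, n_producers = 2,
                                          seed = seed))
    # forward run with known rates defines reachable targets; the
    # calibration must recover them
    flagged <- web5$groups$name[web5$groups$direct_uptake]
    u_true <- stats::setNames(seq_along(flagged), flagged)
    eq_true <- run_to_equilibrium(web5, tracer_params(web5, u_true))
    targets <- body_concentrations(eq_true, web5)[flagged]
    p5 <- calibrate_uptake(web5, targets)
    expect_equal(p5$uptake[flagged], u_true, tolerance = 1e-8)
    achieved <- body_concentrations(run_to_equilibrium(web5, p5),
                                    web5)[flagged]
    expect_equal(unname(achieved), unname(targets), tolerance = 0.01)
  }
})

test_that("unreachable calibration targets name the offending groups", {
  web <- generate_foodweb(web_gen_spec(n_groups = 5, n_producers = 2,
                                       seed = 1))
  # consumers already receive more from their diet than the tiny target
  expect_error(calibrate_uptake(web, c(producer_1 = 10, producer_2 = 10,
                                       consumer_1 = 0.01,
                                       consumer_2 = 0.01)),
               "unreachable.*consumer")
})

test_that("synthetic observations are reproducible and bias-constructed", {
  modelled <- c(a = 10, b = 100)
  o1 <- generate_observations(modelled, bias = 0.3, noise_cv = 0.5,
                              n_studies = 5, seed = 42)
  o2 <- generate_observations(modelled, bias = 0.3, noise_cv = 0.5,
                              n_studies = 5, seed = 42)
  expect_equal(o1, o2)
  expect_equal(nrow(o1), 10)

  # noise-free: every M/O ratio is exactly 1 + bias
  o3 <- generate_observations(modelled, bias = 1, noise_cv = 0,
                              n_studies = 3, seed = 1)
  for (g in names(modelled)) {
    rec <- validation_record(g, modelled[[g]],
                             o3$observed_ug_per_kg[o3$group == g])
    expect_equal(mo_ratio(rec), 2)
  }
  expect_error(generate_observations(modelled, bias = -1), "exceed")
})
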