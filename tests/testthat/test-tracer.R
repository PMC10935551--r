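test_that("rhs reproduces hand arithmetic for the canonical cases", {
  web <- single_producer_web(B = 3, PB = 10, area = 1, depth = 10)
  params <- tracer_params(web, uptake = 1, excretion = 0)

  # at the origin with no influx every derivative vanishes
  s0 <- contaminant_state(web, water_concentration = 0)
  expect_equal(unname(dynamics_rhs(s0, web, params)), c(0, 0))

  # u = 1, C_w = 2, B = 3: uptake is u * C_w * B per unit area (in package
  # units, times 1000 kg/t and the model area)
  s1 <- contaminant_state(web, water_concentration = 2)
  d1 <- dynamics_rhs(s1, web, params)
  expect_equal(unname(d1["producer"]), 1 * 2 * 3 * 1000 * web$area)
  expect_equal(unname(d1["water"]), -unname(d1["producer"]))
})

test_that("the closed system conserves mass in its vector field", {
  web <- mixed_three_group_web()
  params <- tracer_params(web, uptake = c(producer = 2), excretion = 0.1)
  set.seed(11)
  for (k in 1:5) {
    pools <- stats::setNames(abs(rnorm(3, 1e6, 5e5)), web$groups$name)
    st <- contaminant_state(web, water_concentration = 0.3, pools = pools)
    expect_lt(abs(sum(dynamics_rhs(st, web, params, influx = 0))), 1e-5)
    expect_lt(abs(sum(dynamics_rhs(st, web, params, influx = 123)) - 123),
              1e-5)
  }
})

test_that("rhs and the propagator matrix agree on random states", {
  web <- generate_foodweb(web_gen_spec(n_groups = 7, n_producers = 2,
                                       seed = 3))
  params <- tracer_params(web, uptake = 1, excretion = 0.1)
  tm <- hgtrace:::tracer_matrix(web, params)
  set.seed(42)
  for (k in 1:5) {
    x <- abs(rnorm(8, 1e8, 1e8))
    st <- contaminant_state(web, water_concentration = x[1] / tm$volume,
                            pools = x[-1])
    expect_equal(unname(dynamics_rhs(st, web, params)),
                 unname(as.numeric(tm$F %*% x)),
                 tolerance = 1e-10)
  }
})

test_that("single-compartment equilibrium matches the closed form", {
  web <- single_producer_web(B = 3, PB = 10, area = 1, depth = 10)
  # no predation, no detritus: losses are excretion only (turn mortality
  # routing off so the closed form A* = u C_w B / e applies)
  params <- tracer_params(web, uptake = 0.5, excretion = 0.1,
                          detritus_routing = FALSE)
  eq <- run_to_equilibrium(web, params, water_concentration = 2)
  conc <- body_concentrations(eq, web)
  expect_equal(unname(conc), 0.5 * 2 / 0.1, tolerance = 1e-10)

  # the integrating route reaches the same state
  eq2 <- run_to_equilibrium(web, params, water_concentration = 2,
                            method = "integrate")
  expect_equal(eq2$pools, eq$pools, tolerance = 1e-7)

  # zero forcing: the zero state is the equilibrium
  p0 <- tracer_params(web, uptake = 0, excretion = 0.1)
  eq0 <- run_to_equilibrium(web, p0, water_concentration = 0)
  expect_equal(unname(eq0$pools), 0)
})

test_that("equilibrium concentrations are linear in the water concentration", {
  web <- generate_foodweb(web_gen_spec(seed = 2))
  params <- calibrate_uptake(web, default_uptake_targets(web))
  c1 <- body_concentrations(run_to_equilibrium(web, params,
                                               water_concentration = 0.57),
                            web)
  c2 <- body_concentrations(run_to_equilibrium(web, params,
                                               water_concentration = 1.14),
                            web)
  expect_equal(c2, 2 * c1, tolerance = 1e-9)
})

test_that("a pulse release raises the water concentration by mass / volume", {
  web <- mixed_three_group_web()
  params <- tracer_params(web, uptake = c(producer = 1), excretion = 0.1)
  eq <- run_to_equilibrium(web, params, water_concentration = 0.57)
  sc <- exposure_scenario(id = "pulse", background_influx = 0,
                          release_events = data.frame(year = 10, mass_t = 5),
                          area = web$area, depth = web$depth)
  run <- run_scenario(web, params, sc, horizon = 20, init = eq)
  v <- web$area * 1e6 * web$depth * 1e3
  i10 <- which(run$times == 10)
  jump <- run$water_pool[i10] - run$water_pool[i10 - 1]
  drift <- run$water_pool[i10 - 1] - run$water_pool[i10 - 2]
  expect_equal((jump - drift) / v, 5e12 / v, tolerance = 1e-9)
})

test_that("scenario runs stay nonnegative, conserve mass and order by release", {
  web <- generate_foodweb(web_gen_spec(seed = 5))
  params <- calibrate_uptake(web, default_uptake_targets(web))
  eq <- run_to_equilibrium(web, params)
  runs <- lapply(c(0, 1, 10), function(m) {
    sc <- exposure_scenario(
      id = paste0("m", m),
      release_events = if (m > 0) data.frame(year = 25, mass_t = m))
    run_scenario(web, params, sc, horizon = 50, init = eq)
  })
  for (run in runs) {
    expect_true(all(run$pools >= 0) && all(run$water_pool >= 0))
    expect_lt(max(abs(mass_balance(run)$rel_error)), 1e-9)
  }
  f0 <- body_concentrations(runs[[1]])[51, ]
  f1 <- body_concentrations(runs[[2]])[51, ]
  f2 <- body_concentrations(runs[[3]])[51, ]
  expect_true(all(f1 >= f0) && all(f2 >= f1))
  expect_gt(min(f2 - f0), 0)
})

test_that("a release-free scenario reproduces the equilibrium trajectory", {
  web <- mixed_three_group_web()
  params <- tracer_params(web, uptake = c(producer = 1), excretion = 0.1)
  eq <- run_to_equilibrium(web, params, water_concentration = 0.57)
  sc <- exposure_scenario(id = "none", background_influx = 0,
                          area = web$area, depth = web$depth)
  run <- run_scenario(web, params, sc, horizon = 30, init = eq)
  # fixed point of the closed system at zero influx: nothing moves
  expect_equal(max(abs(sweep(run$pools, 2, run$pools[1, ]) /
                         run$pools[1, ])), 0, tolerance = 1e-9)
})

test_that("scenario guards reject malformed forcing", {
  web <- mixed_three_group_web()
  params <- tracer_params(web, uptake = c(producer = 1))
  expect_error(exposure_scenario(release_events =
                                   data.frame(year = 5, mass_t = -1)),
               "nonnegative")
  sc <- exposure_scenario(release_events =
                            data.frame(year = 80, mass_t = 1))
  expect_error(run_scenario(web, params, sc, horizon = 50), "horizon")
})

test_that("tidy export carries the unit-suffixed columns", {
  web <- mixed_three_group_web()
  params <- tracer_params(web, uptake = c(producer = 1))
  run <- run_scenario(web, params, exposure_scenario(), horizon = 5)
  d <- as.data.frame(run)
  expect_named(d, c("time_yr", "compartment", "pool_ug",
                    "body_conc_ug_per_kg", "water_conc_ug_per_L"))
  expect_equal(nrow(d), 6 * 4)    # 6 times x (water + 3 groups)
  expect_true(all(is.na(d$body_conc_ug_per_kg[d$compartment == "water"])))
})

test_that("tracer parameter guards hold and YAML round-trips", {
  web <- mixed_three_group_web()
  expect_error(tracer_params(web, uptake = c(fish = 1)), "direct_uptake")
  expect_error(tracer_params(web, uptake = c(producer = -1)), "nonnegative")
  expect_error(tracer_params(web, uptake = 0, excretion = 1.4), "excretion")
  p <- tracer_params(web, uptake = c(producer = 2.5), excretion = 0.2,
                     assimilation = 0.9)
  path <- tempfile(fileext = ".yml")
  write_tracer_params_yaml(p, path)
  p2 <- read_tracer_params_yaml(path, web)
  expect_equal(p2, p)
  unlink(path)
})
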