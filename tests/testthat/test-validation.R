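test_that("muscle conversion applies the allocation fraction", {
  expect_equal(muscle_concentration(400, 0.5), 200)    # fish
  expect_equal(muscle_concentration(400, 0.15), 60)    # shrimp
  expect_equal(muscle_concentration(123.4, 1), 123.4)  # benthos/plankton
  expect_equal(muscle_concentration(400, 0.5, convention = "divisor"), 800)
  expect_error(muscle_concentration(1, 0), "muscle_fraction")
  expect_error(muscle_concentration(1, 1.2), "muscle_fraction")
})

test_that("M/O ratio compares the model against the observed mean", {
  expect_equal(mo_ratio(validation_record("a", 5, c(5, 5))), 1)
  expect_equal(mo_ratio(validation_record("a", 2, c(1, 1))), 2)
  expect_equal(mo_ratio(validation_record("a", 0.5, 1)), 0.5)
  expect_error(mo_ratio(validation_record("a", 1, c(0, 0))), "positive")
  expect_error(validation_record("a", 1, numeric(0)), "at least one")
})

test_that("NMB is the normalized sum of paired biases", {
  expect_equal(nmb(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nmb(c(3, 1), c(1, 1)), 1)
  expect_equal(nmb(0.8, 1.0), -0.2)
  expect_error(nmb(numeric(0), numeric(0)), "no pairs")
  expect_error(nmb(c(1, 2), 1), "equal length")
  expect_error(nmb(c(1, 1), c(0, 0)), "positive")
})

test_that("NMB interpretation matches the worked factors", {
  over <- nmb_factor(1.2)
  expect_equal(over$direction, "over")
  expect_equal(over$factor, 2.2)
  under <- nmb_factor(-0.2)
  expect_equal(under$direction, "under")
  expect_equal(under$factor, 1.2)
  none <- nmb_factor(0)
  expect_equal(none$factor, 1)
  expect_error(nmb_factor(-1), "exceed")
})

test_that("M/O and NMB are invariant under a common rescaling", {
  set.seed(7)
  m <- runif(6, 1, 10)
  o <- runif(6, 1, 10)
  for (c_scale in c(0.2, 1, 40)) {
    expect_equal(nmb(c_scale * m, c_scale * o), nmb(m, o))
    expect_equal(mo_ratio(validation_record("g", c_scale * m[1],
                                            c_scale * o)),
                 mo_ratio(validation_record("g", m[1], o)))
  }
})

test_that("noise-free constructed observations recover the bias exactly", {
  modelled <- c(cod = 120, herring = 60, shrimp = 15)
  for (b in c(-0.4, 0, 0.5, 1)) {
    obs <- generate_observations(modelled, bias = b, noise_cv = 0,
                                 n_studies = 4, seed = 1)
    m_rep <- modelled[obs$group]
    expect_equal(nmb(m_rep, obs$observed_ug_per_kg), b, tolerance = 1e-12)
  }
})

test_that("food-standard checks use the class-specific limit", {
  std <- food_standard()
  low_ok <- fs_exceedance(0.4, "low", std)
  expect_false(low_ok$exceeded)
  expect_equal(low_ok$margin, 0.1)
  expect_true(fs_exceedance(0.6, "low", std)$exceeded)
  expect_false(fs_exceedance(0.6, "high", std)$exceeded)
  expect_error(fs_exceedance(0.6, "middling", std), "unknown trophic class")
  # monotone in concentration
  conc <- seq(0, 2, by = 0.1)
  flags <- fs_exceedance(conc, rep("high", length(conc)), std)$exceeded
  expect_true(all(diff(flags) >= 0))
})

test_that("dry-weight observations are converted at the boundary", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(group = c("cod", "cod"),
                       study_id = c("s1", "s2"),
                       observed_ug_per_kg = c(100, 500),
                       basis = c("wet", "dry"),
                       moisture_fraction = c(NA, 0.8)),
            path, row.names = FALSE)
  obs <- read_observations(path)
  expect_equal(obs$observed_ug_per_kg, c(100, 100))
  unlink(path)
})

test_that("the validation report assembles per-group statistics", {
  modelled <- c(cod = 100, herring = 50)
  obs <- data.frame(group = c("cod", "cod", "herring"),
                    study_id = c("a", "b", "c"),
                    observed_ug_per_kg = c(100, 150, 40))
  rep <- validation_report(modelled, obs)
  expect_equal(nrow(rep), 2)
  cod <- rep[rep$group == "cod", ]
  expect_equal(cod$mo_ratio, 100 / 125)
  expect_equal(cod$n, 2)
  expect_equal(cod$nmb, (100 - 100 + 100 - 150) / 250)
  expect_equal(cod$direction, "under")
  expect_error(validation_report(c(x = 1), obs), "matches")
})
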