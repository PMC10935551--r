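test_that("consumption matrix implements B * QB * DC bookkeeping", {
  g <- rbind(
    group_row("alga", "producer", B = 5, PB = 30, EE = 0.5),
    group_row("snail", "consumer", B = 10, PB = 2, QB = 5),
    group_row("crab", "consumer", B = 2, PB = 1, QB = 3)
  )
  dc <- rbind(c(0, 0, 0),
              c(1, 0, 0),
              c(0.4, 0.6, 0))
  web <- food_web(g, dc, area = 1, depth = 1)
  q <- consumption_matrix(web)

  # hand arithmetic: B=2, QB=3 on 0.4 of diet -> 2.4; single-prey row sums
  expect_equal(q["crab", "alga"], 2 * 3 * 0.4)
  expect_equal(unname(q["alga", ]), c(0, 0, 0))  # producers consume nothing
  expect_equal(sum(q["snail", ]), 10 * 5)
  expect_equal(unname(rowSums(q)), g$B * g$QB)
  expect_true(all(q >= 0))
})

test_that("mass-balance residuals follow the master equation", {
  # balanced: producer production 100*10*0.5 exactly feeds the grazer 10*50
  web <- two_group_web(grazer_qb = 50)
  res <- mass_balance_residuals(web)
  expect_equal(unname(res["producer"]), 0)
  # grazer: EE = 0, no predators, no landings -> every term vanishes
  expect_equal(unname(res["grazer"]), 0)

  # lowering grazer consumption leaves 100 t km^-2 yr^-1 unused production
  web2 <- two_group_web(grazer_qb = 40)
  expect_equal(unname(mass_balance_residuals(web2)["producer"]), 100)

  # landings enter the balance as removals
  res3 <- mass_balance_residuals(web2, landings = c(100, 0))
  expect_equal(unname(res3["producer"]), 0)
  expect_error(mass_balance_residuals(web, landings = c(1, 2, 3)), "length")
  expect_error(mass_balance_residuals(web, landings = c(-1, 0)),
               "nonnegative")
})

test_that("trophic levels solve the diet-weighted linear system", {
  web <- mixed_three_group_web()
  tl <- trophic_levels(web)
  expect_equal(unname(tl["producer"]), 1)
  expect_equal(unname(tl["zooplankton"]), 2)
  # half on TL 2, half on TL 1 -> 2.5 (hand-solved 3x3 system)
  expect_equal(unname(tl["fish"]), 2.5)
})

test_that("trophic levels agree with fixed-point iteration on random webs", {
  for (seed in 1:10) {
    web <- generate_foodweb(web_gen_spec(n_groups = 8, n_producers = 2,
                                         seed = seed))
    tl <- trophic_levels(web)
    # brute-force oracle: iterate TL <- 1 + DC TL from TL = 1
    tl_it <- rep(1, 8)
    for (k in 1:2000) tl_it <- 1 + as.numeric(web$diet %*% tl_it)
    expect_equal(unname(tl), tl_it, tolerance = 1e-9)
  }
})

test_that("degenerate full-weight cannibalism is rejected", {
  g <- rbind(
    group_row("alga", "producer", B = 5, PB = 30),
    group_row("ouroboros", "consumer", B = 1, PB = 1, QB = 2)
  )
  dc <- rbind(c(0, 0), c(0, 1))   # eats only itself
  web <- food_web(g, dc, area = 1, depth = 1)
  expect_error(trophic_levels(web), "singular")
})

test_that("model invariants are enforced at construction", {
  g <- rbind(
    group_row("alga", "producer", B = 5, PB = 30),
    group_row("snail", "consumer", B = 10, PB = 2, QB = 5)
  )
  dc <- rbind(c(0, 0), c(1, 0))
  expect_silent(food_web(g, dc))

  bad <- g; bad$B[2] <- 0
  expect_error(food_web(bad, dc), "positive")
  bad <- g; bad$QB[2] <- 1      # below PB
  expect_error(food_web(bad, dc), "QB >= PB")
  bad <- g; bad$QB[1] <- 3
  expect_error(food_web(bad, dc), "QB = 0")
  bad <- g; bad$EE[1] <- 1.2
  expect_error(food_web(bad, dc), "EE")
  expect_error(food_web(g, rbind(c(0, 0), c(0.7, 0))), "sum to 1")
  expect_error(food_web(g, rbind(c(0.2, 0), c(1, 0))), "zero")
  expect_error(food_web(g, rbind(c(0, 0), c(1.5, -0.5))), "nonnegative")
})

test_that("webs survive a CSV round trip", {
  web <- generate_foodweb(web_gen_spec(seed = 4))
  gcsv <- tempfile(fileext = ".csv")
  dcsv <- tempfile(fileext = ".csv")
  write_food_web(web, gcsv, dcsv)
  web2 <- read_food_web(gcsv, dcsv, area = web$area, depth = web$depth)
  expect_equal(web2$groups, web$groups)
  expect_equal(web2$diet, web$diet)
  unlink(c(gcsv, dcsv))
})
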