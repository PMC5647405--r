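test_that("mass balance solves EE for hand-checkable webs", {
  # lone producer: no predation, no catch -> EE = 0
  g <- data.frame(name = "p", is_producer = TRUE, is_detritus = FALSE,
                  biomass = 10, pb = 10, qb = 0, ee = NA_real_, catch = 0)
  d <- matrix(0, 1, 1, dimnames = list("p", "p"))
  sol <- balance_model(food_web(g, d))
  expect_equal(unname(sol$ee["p"]), 0)

  # producer + fished consumer: EE from the master equation directly
  sol <- balance_model(toy_web(consumer_catch = 0.5))
  expect_equal(unname(sol$ee["prod"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(sol$ee["cons"]), 0.5, tolerance = 1e-12)
  expect_true(sol$balanced)

  # overharvest: EE > 1 flags the solution unbalanced without erroring
  sol2 <- balance_model(toy_web(consumer_catch = 1.5))
  expect_equal(unname(sol2$ee["cons"]), 1.5, tolerance = 1e-12)
  expect_false(sol2$balanced)
})

test_that("balance residuals vanish and biomass/EE solving round-trips", {
  web <- default_web()
  sol <- balance_model(web)
  g <- web$groups
  living <- !g$is_detritus
  # master equation residual per living group
  resid <- sol$biomass * g$pb * sol$ee - rowSums(sol$q0) - g$catch
  expect_lt(max(abs(resid[living])), 1e-8)
  expect_true(all(sol$ee[living] >= 0 & sol$ee[living] <= 1))

  # feed the solved EE back and blank one biomass: recover the same number
  for (nm in c("predator", "foragefish", "zooplankton")) {
    web2 <- web
    i <- match(nm, web2$groups$name)
    web2$groups$ee[i] <- sol$ee[nm]
    web2$groups$biomass[i] <- NA_real_
    sol2 <- balance_model(web2)
    expect_equal(unname(sol2$biomass[nm]), unname(sol$biomass[nm]),
                 tolerance = 1e-8)
  }
})

test_that("mortality budget decomposes P/B exactly", {
  sol <- balance_model(toy_web())
  mb <- mortality_budget(sol)
  p <- mb[mb$group == "prod", ]
  expect_equal(p$predation, 0.5)   # 5 / 10
  expect_equal(p$fishing, 0)
  expect_equal(p$other, 9.5)       # 10 * (1 - 0.05)

  # group at EE = 1 has no other mortality: set catch = production
  g <- data.frame(name = c("p", "c"), is_producer = c(TRUE, FALSE),
                  is_detritus = FALSE, biomass = c(10, 1), pb = c(10, 1),
                  qb = c(0, 5), ee = NA_real_, catch = c(0, 1))
  d <- matrix(c(0, 0, 1, 0), 2, 2, dimnames = list(g$name, g$name))
  solc <- balance_model(food_web(g, d))
  expect_equal(unname(solc$ee["c"]), 1)
  expect_equal(mortality_budget(solc)$other[2], 0)

  # property: components always sum to P/B on the generated web
  web <- default_web()
  s <- balance_model(web)
  mb2 <- mortality_budget(s)
  pb <- web$groups$pb[!web$groups$is_detritus]
  expect_lt(max(abs(mb2$predation + mb2$fishing + mb2$other - pb)), 1e-8)
})

test_that("model validation rejects malformed definitions", {
  g <- toy_web()$groups
  d <- toy_web()$diet
  # diet column not summing to 1
  d_bad <- d; d_bad["prod", "cons"] <- 0.6
  expect_error(food_web(g, d_bad), "sum to 1")
  # two unknowns in one group
  g2 <- g; g2$biomass[2] <- NA
  expect_error(food_web(g2, d), "at most one")
  # producer with consumption
  g3 <- g; g3$qb[1] <- 2
  expect_error(food_web(g3, d), "qb = 0")
  # negative solved biomass -> error (demand exceeds production)
  g4 <- g; g4$biomass[2] <- NA; g4$ee[2] <- 0.5; g4$catch[2] <- -1
  expect_error(food_web(g4, d), "catch")
})

test_that("singular unknown-biomass systems are reported, not solved", {
  # self-feeding consumer whose balance coefficient cancels exactly
  g <- data.frame(name = c("p", "c"), is_producer = c(TRUE, FALSE),
                  is_detritus = FALSE,
                  biomass = c(10, NA), pb = c(10, 1), qb = c(0, 1),
                  ee = c(NA, 0.5), catch = c(0, 0))
  d <- matrix(c(0, 0, 0.5, 0.5), 2, 2, dimnames = list(g$name, g$name))
  expect_error(balance_model(food_web(g, d)), "singular|circular")
})
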