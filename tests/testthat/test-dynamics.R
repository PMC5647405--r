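sim_setup <- function() {
  web <- default_web()
  sol <- balance_model(web)
  arena <- calibrate_arena(sol, v = web$vulnerability, d = web$handling)
  list(web = web, sol = sol, arena = arena)
}

test_that("the mass-balance baseline is a fixed point of the dynamics", {
  s <- sim_setup()
  f <- forcing_set(2000:2049)  # no thermal/pp forcing, baseline F
  run <- simulate_web(s$web, s$sol, s$arena, f)
  drift <- abs(run$biomass[50, ] / s$sol$biomass - 1)
  expect_lt(max(drift), 1e-6)
})

test_that("doubling F on the top predator depresses it and releases its prey", {
  s <- sim_setup()
  yrs <- 2000:2009
  f2 <- s$sol$f0
  fmat <- matrix(rep(f2, each = 10), 10, 6,
                 dimnames = list(yrs, names(f2)))
  fmat[, "predator"] <- 2 * f2["predator"]
  run <- simulate_web(s$web, s$sol, s$arena, forcing_set(yrs, f_mort = fmat))
  pred <- run$biomass[, "predator"]
  expect_true(all(diff(pred[1:8]) < 0))   # settles to a depressed level
  expect_lt(pred[10], 0.75 * s$sol$biomass["predator"])
  expect_gt(run$biomass[10, "foragefish"], s$sol$biomass["foragefish"])
})

test_that("halving the step barely changes the trajectory, reruns are identical", {
  s <- sim_setup()
  yrs <- 2000:2014
  fmat <- matrix(rep(s$sol$f0, each = 15), 15, 6,
                 dimnames = list(yrs, names(s$sol$f0)))
  fmat[, "predator"] <- 1.5 * s$sol$f0["predator"]
  f <- forcing_set(yrs, temperature = seq(9.5, 10.5, length.out = 15),
                   f_mort = fmat)
  run1 <- simulate_web(s$web, s$sol, s$arena, f, steps_per_year = 12)
  run2 <- simulate_web(s$web, s$sol, s$arena, f, steps_per_year = 24)
  expect_lt(max(abs(run2$biomass / run1$biomass - 1)), 1e-3)
  run1b <- simulate_web(s$web, s$sol, s$arena, f, steps_per_year = 12)
  expect_identical(run1$biomass, run1b$biomass)
})

test_that("annual catch integrates F times mean biomass", {
  s <- sim_setup()
  run <- simulate_web(s$web, s$sol, s$arena, forcing_set(2000:2019))
  expect_equal(run$catch[15, "predator"],
               s$sol$f0["predator"] * run$biomass[15, "predator"],
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("a zero-length horizon yields an empty trajectory", {
  s <- sim_setup()
  run <- simulate_web(s$web, s$sol, s$arena, forcing_set(integer(0)))
  expect_identical(nrow(run$biomass), 0L)
  expect_identical(length(run$years), 0L)
})

test_that("sustained warming above a consumer optimum shifts the equilibrium", {
  # three-group chain: warming cuts consumer intake, so the consumer falls
  # and its producer prey rises relative to the cool run
  web <- chain_web()
  sol <- balance_model(web)
  arena <- calibrate_arena(sol, v = web$vulnerability, d = web$handling)
  yrs <- 2000:2039
  t_opt <- web$thermal$consumer$t_opt
  cool <- simulate_web(web, sol, arena,
                       forcing_set(yrs, temperature = rep(t_opt, 40)))
  warm <- simulate_web(web, sol, arena,
                       forcing_set(yrs, temperature = rep(t_opt + 2.5, 40)))
  expect_lt(warm$biomass[40, "consumer"], cool$biomass[40, "consumer"])
  expect_gt(warm$biomass[40, "producer"], cool$biomass[40, "producer"])
})

test_that("feeding-time adaptation stays clamped and off by default", {
  s <- sim_setup()
  f <- forcing_set(2000:2009, temperature = rep(11.5, 10))
  run0 <- simulate_web(s$web, s$sol, s$arena, f)
  expect_true(all(run0$t_rel == 1))
  run1 <- simulate_web(s$web, s$sol, s$arena, f, alpha = 0.3)
  expect_true(all(run1$t_rel >= 0.1 & run1$t_rel <= 2))
  # warming starves the boreal predator: it should forage longer
  expect_gt(run1$t_rel["predator"], 1)
})
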