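mc_setup <- function() {
  web <- default_web()
  sol <- balance_model(web)
  arena <- calibrate_arena(sol, v = web$vulnerability, d = web$handling)
  yrs <- 2000:2014
  list(web = web, sol = sol, arena = arena,
       forcing = forcing_set(yrs, temperature = seq(9.5, 10, length.out = 15)))
}

test_that("zero input uncertainty collapses the envelope onto the baseline", {
  s <- mc_setup()
  ped0 <- pedigree_fixed(s$web, cv = 0)
  env <- monte_carlo(s$web, s$sol, s$arena, s$forcing, ped0,
                     n_trials = 20, seed = 5)
  expect_equal(env$biomass$p5, env$biomass$p95, tolerance = 1e-12)
  base <- simulate_web(s$web, s$sol, s$arena, s$forcing)
  expect_equal(env$biomass$p50, base$biomass, tolerance = 1e-10)
})

test_that("fixed-CV sampling keeps every draw within the stated band", {
  s <- mc_setup()
  ped <- pedigree_fixed(s$web, cv = 0.10)
  env <- monte_carlo(s$web, s$sol, s$arena, s$forcing, ped,
                     n_trials = 30, seed = 6)
  expect_true(all(env$draws >= 0.9 - 1e-9 & env$draws <= 1.1 + 1e-9,
                  na.rm = TRUE))
  expect_true(all(env$biomass$p5 <= env$biomass$p50 + 1e-12))
  expect_true(all(env$biomass$p50 <= env$biomass$p95 + 1e-12))
})

test_that("envelopes are seed-reproducible and widen with the CV", {
  s <- mc_setup()
  ped <- pedigree_fixed(s$web, cv = 0.05)
  e1 <- monte_carlo(s$web, s$sol, s$arena, s$forcing, ped,
                    n_trials = 25, seed = 7)
  e2 <- monte_carlo(s$web, s$sol, s$arena, s$forcing, ped,
                    n_trials = 25, seed = 7)
  expect_identical(e1$biomass$p95, e2$biomass$p95)
  e3 <- monte_carlo(s$web, s$sol, s$arena, s$forcing, ped,
                    n_trials = 25, seed = 8)
  expect_false(identical(e1$biomass$p95, e3$biomass$p95))

  width <- function(cv) {
    e <- monte_carlo(s$web, s$sol, s$arena, s$forcing,
                     pedigree_fixed(s$web, cv = cv), n_trials = 25, seed = 9)
    mean(e$biomass$p95 - e$biomass$p5)
  }
  w <- vapply(c(0, 0.05, 0.10), width, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("the P/B confidence cap is enforced in pedigree mode", {
  ped <- pedigree(c("a", "b"), cv_b = 0.4, cv_pb = 0.5, cv_qb = 0.3,
                  cv_ee = 0.2)
  expect_true(all(ped$cv_pb <= 0.1))
  expect_error(pedigree("a", cv_b = 0.9), "0.8")
})

test_that("chronological splits reproduce the three validation schemes", {
  yrs <- 1985:2013  # 29-year span
  obs <- data.frame(group = "g", kind = "biomass", year = yrs,
                    value = exp(rnorm(29)))
  for (cfg in list(list(s = "A", fit = 22, hold = 7),
                   list(s = "B", fit = 24, hold = 5),
                   list(s = "C", fit = 26, hold = 3))) {
    sp <- validation_split(obs, cfg$s)
    expect_equal(nrow(sp$fit), cfg$fit)
    expect_equal(nrow(sp$holdout), cfg$hold)
    expect_identical(sort(c(sp$fit$year, sp$holdout$year)), yrs)
    expect_identical(sp$holdout$year, tail(yrs, cfg$hold))
    # explicit hold-out length reproduces the named scheme
    sp2 <- validation_split(obs, cfg$hold)
    expect_identical(sp2$fit, sp$fit)
  }
  short <- obs[obs$year < 2010, ]
  expect_error(validation_split(short, "A"), "29")
})

test_that("RMSD identities hold on the natural scale", {
  yrs <- 2001:2010
  mat <- matrix(seq(2, 4, length.out = 10), 10, 1,
                dimnames = list(yrs, "g"))
  run <- fake_run(yrs, mat)
  obs <- data.frame(group = "g", kind = "biomass", year = yrs,
                    value = mat[, 1])
  expect_equal(rmsd(run, obs)$rmsd, 0)

  # constant offset d -> RMSD |d|
  obs_d <- transform(obs, value = value + 0.37)
  expect_equal(rmsd(run, obs_d)$rmsd, 0.37, tolerance = 1e-12)

  # pooled value over two equal-length series
  mat2 <- cbind(g = mat[, 1], h = mat[, 1])
  run2 <- fake_run(yrs, mat2)
  obs2 <- rbind(obs_d,
                data.frame(group = "h", kind = "biomass", year = yrs,
                           value = mat[, 1] + 0.1))
  r <- rmsd(run2, obs2)
  expect_equal(attr(r, "pooled"),
               sqrt((0.37^2 + 0.1^2) / 2), tolerance = 1e-12)
  expect_error(rmsd(run, obs[0, ]), "overlap")
})
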