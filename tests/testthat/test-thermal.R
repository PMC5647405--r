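test_that("response is 1 at the optimum and matches the two-species oracle", {
  nc <- thermal_niche(13.8, 3, 3)
  expect_identical(thermal_response(nc, 13.8), 1)

  # sigmas back-computed from the published scaling-factor pair at 10.5 C:
  # a warm-optimum eurytherm reading 0.54 and a cold-optimum boreal species
  # reading 0.70
  s_warm <- (13.8 - 10.5) / sqrt(-2 * log(0.54))
  warm <- thermal_niche(13.8, sigma_lower = s_warm, sigma_upper = 3)
  expect_equal(thermal_response(warm, 10.5), 0.54, tolerance = 0.005)

  s_cold <- (10.5 - 4.6) / sqrt(-2 * log(0.70))
  cold <- thermal_niche(4.6, sigma_lower = 2, sigma_upper = s_cold)
  expect_equal(thermal_response(cold, 10.5), 0.70, tolerance = 0.005)

  expect_error(thermal_response(nc, NaN), "finite")
})

test_that("response is in (0,1], peaks only at t_opt, monotone on each side", {
  set.seed(1)
  for (i in 1:25) {
    nc <- thermal_niche(runif(1, -2, 20), runif(1, 0.5, 6), runif(1, 0.5, 6))
    below <- sort(nc$t_opt - 10^seq(-3, 1, length.out = 12))
    above <- sort(nc$t_opt + 10^seq(-3, 1, length.out = 12))
    r <- thermal_response(nc, c(below, nc$t_opt, above))
    expect_true(all(r > 0 & r <= 1))
    expect_equal(r[13], 1)
    expect_true(all(diff(r[1:13]) > 0))    # rising toward the optimum
    expect_true(all(diff(r[13:25]) < 0))   # falling beyond it
  }
})

test_that("build_niche follows the percentile-averaging rule", {
  # optimum = mean of 10th and 90th percentiles
  nc <- build_niche(5, 10, 17.6, 25)
  expect_equal(nc$t_opt, 13.8)

  # sigmas place the envelope edges k_sigma standard deviations out
  nc2 <- build_niche(0, 4, 8, 18, k_sigma = 2)
  expect_equal(nc2$t_opt, 6)
  expect_equal(nc2$sigma_lower, 3)
  expect_equal(nc2$sigma_upper, 6)
  expect_equal(thermal_response(nc2, 6), 1)

  # degenerate envelope gets the floor width
  nc3 <- build_niche(8, 8, 8, 8)
  expect_equal(nc3$t_opt, 8)
  expect_equal(nc3$sigma_lower, 0.5)
  expect_equal(nc3$sigma_upper, 0.5)

  expect_error(build_niche(10, 5, 8, 12), "<=")
})

test_that("aggregation takes weighted geometric means of the envelope", {
  a <- build_niche(2, 4, 8, 10)
  b <- build_niche(5, 10, 20, 40)
  # two species with t_max 10 and 40, equal weights -> sqrt(10 * 40)
  agg <- aggregate_niches(list(a, b), c(1, 1))
  expect_equal(agg$t_max, 20)

  # identity and degenerate-weight cases
  same <- aggregate_niches(list(a, a, a), c(2, 1, 3))
  expect_equal(same$t_opt, a$t_opt)
  expect_equal(same$sigma_lower, a$sigma_lower)
  only_a <- aggregate_niches(list(a, b), c(1, 0))
  expect_equal(only_a$t_max, a$t_max)
  expect_equal(only_a$t_opt, a$t_opt)

  # order invariance
  ab <- aggregate_niches(list(a, b), c(0.3, 0.7))
  ba <- aggregate_niches(list(b, a), c(0.7, 0.3))
  expect_equal(ab$t_opt, ba$t_opt)
  expect_error(aggregate_niches(list(a, b), c(0, 0)), "zero")

  # sub-zero temperatures are shifted positive before log-averaging
  cold <- build_niche(-2, 0, 2, 4)
  expect_silent(aggregate_niches(list(cold, a), c(1, 1)))
})

test_that("juvenile offset translates the niche rigidly", {
  nc <- build_niche(2, 5, 7, 12)
  up <- juvenile_offset(nc, 1)
  expect_equal(up$t_opt, nc$t_opt + 1)
  expect_equal(up$sigma_lower, nc$sigma_lower)
  expect_equal(juvenile_offset(nc, 0)$t_opt, nc$t_opt)
  temps <- seq(0, 15, by = 0.5)
  expect_equal(thermal_response(up, temps + 1), thermal_response(nc, temps))
})
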