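test_that("DIT derivation subtracts the surface-to-bottom offset", {
  sst <- climate_series(1990:1999, rep(12, 10), "SST")
  expect_equal(dit_from_sst(sst, 0)$value, sst$value)
  dit <- dit_from_sst(sst, 0.61)
  expect_equal(dit$value, rep(11.39, 10))
  expect_equal(dit$value + 0.61, sst$value)
})

test_that("mirroring reflects the smoothed record around the pivot", {
  yrs <- 1900:2012
  sm <- climate_series(yrs, sin(2 * pi * (yrs - 1940) / 62))
  proj <- mirror_amo(sm, pivot_year = 2012, end_year = 2100)
  expect_equal(proj$value[proj$year == 2012], sm$value[sm$year == 2012])
  for (k in c(1, 10, 40, 88))
    expect_equal(proj$value[proj$year == 2012 + k],
                 sm$value[sm$year == 2012 - k])
  # historical part untouched
  expect_equal(proj$value[proj$year <= 2012], sm$value)

  # successive projected minima spaced like the historical cycle
  fut <- proj[proj$year > 2012, ]
  mins <- fut$year[which(diff(sign(diff(fut$value))) == 2) + 1]
  if (length(mins) >= 2) expect_true(all(diff(mins) >= 60 & diff(mins) <= 65))
  # reflections beyond the record wrap by the recurrence interval
  shorty <- climate_series(1990:2012, sin(2 * pi * (1990:2012) / 62))
  expect_silent(mirror_amo(shorty, 2012, 2100))
})

test_that("future temperature is the exact sum of its parts", {
  hist <- climate_series(1984:2013, 9 + 0.02 * (0:29) + sin(0:29))
  yrs <- 2014:2100
  anom <- rcp_anomaly_series(yrs, "rcp45")
  amo <- climate_series(yrs, 0.2 * sin(2 * pi * (yrs - 2014) / 62))

  # degenerate composition: constant at the last historical value
  flat <- build_future_temperature(hist, climate_series(yrs, rep(0, 87)),
                                   NULL, include_variability = FALSE)
  expect_equal(flat$value, rep(hist$value[30], 87))

  # additivity in the oscillation component
  t1 <- build_future_temperature(hist, anom, amo, seed = 3)
  amo2 <- climate_series(yrs, 2 * amo$value)
  t2 <- build_future_temperature(hist, anom, amo2, seed = 3)
  expect_equal(t2$value - t1$value, amo$value)
  comp <- attr(t1, "components")
  expect_equal(comp$base + comp$anomaly + comp$variability + comp$amo,
               t1$value)

  # a linear +0.03 C/yr anomaly accumulates ~2.6 C over 87 years
  lin <- climate_series(yrs, 0.03 * (yrs - yrs[1]))
  tl <- build_future_temperature(hist, lin, NULL,
                                 include_variability = FALSE)
  expect_equal(tl$value[87] - tl$value[1], 0.03 * 86, tolerance = 1e-12)

  # deterministic given the seed
  expect_identical(build_future_temperature(hist, anom, amo, seed = 3)$value,
                   t1$value)
})

test_that("warming-intensity stand-ins are ordered and zero-referenced", {
  yrs <- 2014:2100
  ends <- vapply(c("rcp26", "rcp45", "rcp65", "rcp85"), function(s) {
    a <- rcp_anomaly_series(yrs, s)
    expect_equal(a$value[1], 0)
    a$value[87]
  }, numeric(1))
  expect_true(all(diff(ends) > 0))
})

test_that("projections splice smoothly and respond in the expected direction", {
  web <- default_web()
  sol <- balance_model(web)
  arena <- calibrate_arena(sol, v = web$vulnerability, d = web$handling)
  hind_yrs <- 1990:2013
  t_hind <- rep(9.6, length(hind_yrs))
  hind <- simulate_web(web, sol, arena,
                       forcing_set(hind_yrs, temperature = t_hind))
  f_last <- sol$f0[c("foragefish", "predator")]

  # frozen F and T continue the hindcast without a jump
  frozen <- scenario_spec("frozen", f_last,
                          climate_series(2014:2053, rep(9.6, 40)),
                          2014, 2053)
  res <- project_scenario(web, sol, arena, frozen,
                          state0 = hind$final_state, f_start = sol$f0)
  expect_lt(abs(res$run$biomass[1, "predator"] /
                  hind$biomass[length(hind_yrs), "predator"] - 1), 0.02)

  # warming beyond the boreal predator optimum vs constant temperature
  warm <- scenario_spec("warm", f_last,
                        climate_series(2014:2053,
                                       seq(9.6, 13.5, length.out = 40)),
                        2014, 2053)
  res_w <- project_scenario(web, sol, arena, warm,
                            state0 = hind$final_state, f_start = sol$f0)
  expect_lt(res_w$run$biomass[40, "predator"],
            0.8 * res$run$biomass[40, "predator"])

  # fishing at F_MSY < F_status_quo rebuilds an overfished stock
  f_over <- f_last; f_over["predator"] <- 0.6   # overfished status quo
  f_msy <- f_last; f_msy["predator"] <- 0.19
  sq <- project_scenario(web, sol, arena,
                         scenario_spec("sq", f_over, NULL, 2014, 2053),
                         state0 = hind$final_state, f_start = sol$f0)
  msy <- project_scenario(web, sol, arena,
                          scenario_spec("msy", f_msy, NULL, 2014, 2053),
                          state0 = hind$final_state, f_start = sol$f0)
  expect_gt(msy$run$biomass[40, "predator"], sq$run$biomass[40, "predator"])

  # unknown group in the F table is a user error
  bad <- scenario_spec("bad", c(unicorn = 0.1), NULL, 2014, 2020)
  expect_error(project_scenario(web, sol, arena, bad), "unicorn")

  # ramped F approaches the target gradually
  ramped <- scenario_spec("ramp", f_msy, NULL, 2014, 2053, f_ramp = 0.15)
  rr <- project_scenario(web, sol, arena, ramped,
                         state0 = hind$final_state, f_start = f_over)
  expect_gt(rr$run$catch[1, "predator"] / rr$run$biomass[1, "predator"],
            f_msy["predator"])
})

test_that("cumulative percent decreases match the reporting arithmetic", {
  expect_identical(cumulative_change(15.8, 13.5), 15)
  expect_identical(cumulative_change(3.04, 2.42), 20)
  expect_identical(cumulative_change(7, 7), 0)
  expect_error(cumulative_change(0, 1), "> 0")
})
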