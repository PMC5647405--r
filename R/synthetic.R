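#' Specification for a synthetic food-web experiment
#'
#' Defines the ground truth of a generated test system: web size, the
#' planted per-predator vulnerabilities (top-down control), the planted
#' primary-production anomaly, observation noise, and the simulated span
#' (default 29 years, a typical length of fisheries assessment series).
#'
#' @param n_groups 3 (producer-consumer-detritus chain) or 6 (producer,
#'   detritus, zooplankton, two mid-trophic consumers, top predator).
#' @param planted_v named vector of true vulnerabilities by predator
#'   (default: top predator at 50, strong top-down control; everyone else
#'   at the neutral 2).
#' @param anomaly_values true production-anomaly spline knot values
#'   (default 3 knots).
#' @param noise_cv lognormal CV of observation noise (default 0.1).
#' @param years series length (default 29).
#' @param start_year first year (default 1985).
#' @param seed RNG seed; fully determines the generated data.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_groups = 6, planted_v = NULL,
                           anomaly_values = c(1.1, 0.9, 1.05),
                           noise_cv = 0.1, years = 29, start_year = 1985,
                           seed = 42L) {
  if (!n_groups %in% c(3, 6)) stop("n_groups must be 3 or 6")
  if (is.null(planted_v))
    planted_v <- c(predator = 50)
  structure(list(n_groups = n_groups, planted_v = planted_v,
                 anomaly_values = anomaly_values, noise_cv = noise_cv,
                 years = years, start_year = start_year,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a balanced synthetic food web
#'
#' Builds a small shelf-sea-like web whose mass balance is feasible by
#' construction (all EE in [0, 1], maximum about 0.7). The 6-group preset
#' has a phytoplankton producer, a detritus pool, zooplankton, a
#' zooplanktivorous forage fish, a detritivorous benthos group and a fished
#' piscivorous top predator. Thermal envelopes contrast a boreal
#' stenotherm (the predator: low optimum, narrow tolerance, sitting on the
#' upper flank of its niche at the simulated temperatures) with a
#' eurytherm (the forage fish: high optimum, wide tolerance); the plankton
#' groups get wide niches centred on the mean simulated temperature.
#'
#' @param spec a [synthetic_spec()].
#' @return a [food_web()].
#' @export
make_web <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t_mean <- 9.5  # mean of the synthetic temperature series, deg C
  if (spec$n_groups == 3) {
    groups <- data.frame(
      name = c("producer", "consumer", "detritus"),
      is_producer = c(TRUE, FALSE, FALSE),
      is_detritus = c(FALSE, FALSE, TRUE),
      biomass = c(30, 5, 100),
      pb = c(20, 1.5, 0),
      qb = c(0, 6, 0),
      ee = NA_real_,
      catch = c(0, 0.9, 0))
    diet <- matrix(0, 3, 3, dimnames = list(groups$name, groups$name))
    diet["producer", "consumer"] <- 1
    thermal <- list(
      consumer = thermal_niche(9.3, 2, 1.2),
      producer = plankton_niche(t_mean))
    return(food_web(groups, diet, thermal = thermal))
  } else {
    groups <- data.frame(
      name = c("phytoplankton", "detritus", "zooplankton", "foragefish",
               "benthos", "predator"),
      is_producer = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      is_detritus = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
      biomass = c(30, 150, 15, 6, 10, 1.5),
      pb = c(20, 0, 8, 1.3, 2.5, 0.5),
      qb = c(0, 0, 30, 5.2, 10, 2),
      ee = NA_real_,
      catch = c(0, 0, 0, 0.6, 0.5, 0.45))
    diet <- matrix(0, 6, 6, dimnames = list(groups$name, groups$name))
    diet["phytoplankton", "zooplankton"] <- 0.9
    diet["detritus", "zooplankton"] <- 0.1
    diet["zooplankton", "foragefish"] <- 1
    diet["detritus", "benthos"] <- 0.85
    diet["phytoplankton", "benthos"] <- 0.15
    diet["foragefish", "predator"] <- 0.6
    diet["benthos", "predator"] <- 0.4
    thermal <- list(
      predator = thermal_niche(9.3, 2, 2),        # boreal stenotherm
      foragefish = thermal_niche(11, 6, 4),       # eurytherm
      benthos = thermal_niche(9.8, 5, 5),
      zooplankton = plankton_niche(t_mean),
      phytoplankton = plankton_niche(t_mean))
  }
  # plankton feeding links turn over too fast for a strong
  # predator-saturation term
  food_web(groups, diet, thermal = thermal,
           config = list(handling = c(zooplankton = Inf, foragefish = 5)))
}

#' Synthetic temperature series: trend + multidecadal oscillation + noise
#'
#' @param spec a [synthetic_spec()].
#' @param trend warming trend, deg C per year (default 0.03).
#' @param osc_amp,osc_period oscillation amplitude (deg C) and period
#'   (years; default 62, a basin-oscillation-like cycle).
#' @param noise_sd white-noise SD, deg C.
#' @return a [climate_series()] (uses the spec's seed; deterministic).
#' @export
make_temperature <- function(spec, trend = 0.03, osc_amp = 0.3,
                             osc_period = 62, noise_sd = 0.15) {
  set.seed(spec$seed + 1L)
  yrs <- spec$start_year + seq_len(spec$years) - 1L
  t0 <- seq_along(yrs) - 1
  v <- 9.5 + trend * t0 + osc_amp * sin(2 * pi * t0 / osc_period) +
    rnorm(length(yrs), 0, noise_sd)
  climate_series(yrs, v, label = "synthetic DIT")
}

#' Generate noisy observations with known ground truth
#'
#' Runs the forward model under the planted vulnerabilities, the planted
#' production anomaly, a mild rising trend in fishing mortality on the
#' fished groups, and the synthetic temperature series, then multiplies
#' the trajectories by lognormal observation noise (mean 1, CV
#' `noise_cv`). Biomass series for all living groups and catch series for
#' the fished groups are observed.
#'
#' @param spec a [synthetic_spec()].
#' @param web the [make_web()] output (rebuilt when `NULL`).
#' @return list with `observed` (observation table), `forcing` (the
#'   [forcing_set()] to fit with: temperature + fishing, no anomaly),
#'   `truth` (planted vulnerabilities, anomaly, noise-free trajectories,
#'   anomaly series by year), `web`, `sol`.
#' @export
make_observations <- function(spec, web = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(web)) web <- make_web(spec)
  sol <- balance_model(web)
  yrs <- spec$start_year + seq_len(spec$years) - 1L
  temp <- make_temperature(spec)
  g <- web$groups

  fished <- g$name[g$catch > 0]
  ny <- length(yrs)
  ramp <- seq(0, 1, length.out = ny)
  fmat <- sapply(fished, function(nm) sol$f0[nm] * (1 + 0.3 * ramp))
  dimnames(fmat) <- list(yrs, fished)

  forcing <- forcing_set(yrs, temperature = cs_value(temp, yrs),
                         f_mort = fmat)
  window <- range(yrs)
  anom <- if (length(spec$anomaly_values) > 0)
    spline_anomaly(spec$anomaly_values, window) else spline_anomaly()
  v_by <- spec$planted_v
  missing_pred <- setdiff(names(v_by), g$name)
  if (length(missing_pred) > 0 && spec$n_groups == 3)
    names(v_by) <- "consumer"
  run <- fit_simulate(web, sol, forcing, v_by = v_by, anomaly = anom)

  set.seed(spec$seed + 2L)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  obs <- list()
  noisy <- function(x) x * exp(rnorm(length(x), -sdlog^2 / 2, sdlog))
  for (nm in g$name[!g$is_detritus])
    obs[[length(obs) + 1L]] <- data.frame(
      group = nm, kind = "biomass", year = yrs,
      value = noisy(run$biomass[, nm]), weight = 1)
  for (nm in fished)
    obs[[length(obs) + 1L]] <- data.frame(
      group = nm, kind = "catch", year = yrs,
      value = noisy(run$catch[, nm]), weight = 1)
  observed <- do.call(rbind, obs)

  list(observed = observed, forcing = forcing,
       truth = list(v = v_by, anomaly = anom,
                    anomaly_series = anomaly_multiplier(anom, yrs),
                    trajectory = run, temperature = temp),
       web = web, sol = sol)
}
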