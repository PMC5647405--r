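#' Annual climate series
#'
#' A labelled annual series (temperature in deg C, or index units for
#' oscillation indices) with strictly consecutive years.
#'
#' @param year integer years (consecutive).
#' @param value numeric values.
#' @param label series label.
#' @return data.frame of class `climate_series` with columns `year`, `value`.
#' @export
climate_series <- function(year, value, label = "") {
  year <- as.integer(year)
  stopifnot(length(year) == length(value))
  if (length(year) > 1L && any(diff(year) != 1L))
    stop("years must be strictly increasing with no gaps")
  structure(data.frame(year = year, value = as.numeric(value)),
            label = label, class = c("climate_series", "data.frame"))
}

cs_value <- function(cs, yrs) cs$value[match(yrs, cs$year)]

#' Depth-integrated temperature from sea-surface temperature
#'
#' Near-bottom shelf water is cooler than the surface by an approximately
#' constant offset; the depth-integrated temperature (DIT) used to force
#' the model is the SST series shifted down by that offset (0.61 deg C for
#' the west-of-Scotland shelf). A multiplicative mode (`mode = "scale"`,
#' value times `1 - offset/mean`) is provided for sensitivity checks.
#'
#' @param sst a [climate_series()] of SST, deg C.
#' @param offset surface-to-bottom offset, deg C (default 0.61).
#' @param mode "subtract" (default) or "scale".
#' @return a [climate_series()] of DIT.
#' @export
dit_from_sst <- function(sst, offset = 0.61, mode = c("subtract", "scale")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(offset))
  v <- if (mode == "subtract") sst$value - offset
  else sst$value * (1 - offset / mean(sst$value))
  climate_series(sst$year, v, label = "DIT")
}

#' Project an oscillation index by time reflection ("mirroring")
#'
#' Future values re-play the smoothed historical pattern backwards from a
#' pivot year: projection(pivot + k) = smoothed(pivot - k). This lets
#' historical phases of a quasi-periodic index (e.g. a ~60-70-year basin
#' oscillation) recur in the projection. When the reflection would reach
#' before the start of the record, the lookup wraps forward by the
#' configured recurrence interval.
#'
#' @param smoothed a [climate_series()] of the smoothed historical index.
#' @param pivot_year reflection pivot (must lie within the series).
#' @param end_year last projected year.
#' @param recurrence wrap interval in years for reflections that run off
#'   the start of the record (default 62).
#' @return a [climate_series()] spanning the historical years through
#'   `end_year`; historical values unchanged.
#' @export
mirror_amo <- function(smoothed, pivot_year, end_year, recurrence = 62) {
  if (!pivot_year %in% smoothed$year) stop("pivot year outside series")
  hist_keep <- smoothed[smoothed$year <= pivot_year, ]
  ks <- seq_len(end_year - pivot_year)
  src <- pivot_year - ks
  y0 <- min(smoothed$year)
  while (any(src < y0)) src[src < y0] <- src[src < y0] + recurrence
  proj <- cs_value(smoothed, src)
  climate_series(c(hist_keep$year, pivot_year + ks),
                 c(hist_keep$value, proj),
                 label = paste0(attr(smoothed, "label"), " mirrored"))
}

#' Compose a future temperature series (anomaly + variability + oscillation)
#'
#' Future temperature is built additively from the last historical
#' depth-integrated temperature: T(y) = DIT_last + anomaly(y) +
#' variability(y) + AMO(y). The anomaly is a warming-scenario series
#' referenced to 0 in its first year; the variability term re-creates the
#' historical interannual scatter with a seeded Gaussian draw whose
#' standard deviation follows a moving-window (default 3-year) estimate of
#' the detrended historical residual SD, recycled over the projection; the
#' oscillation term is, e.g., a mirrored index projection (0 if `NULL`).
#'
#' @param hist_dit historical DIT [climate_series()].
#' @param rcp_anomaly anomaly series (deg C, first value 0) over the
#'   projection years.
#' @param amo_projection optional oscillation series covering the
#'   projection years.
#' @param stdev_window moving-window length, years (default 3).
#' @param seed RNG seed for the variability draw (deterministic given seed).
#' @param include_variability set FALSE for a noise-free composition.
#' @return a [climate_series()] over the projection years, with the three
#'   components retained in attribute `components`.
#' @export
build_future_temperature <- function(hist_dit, rcp_anomaly,
                                     amo_projection = NULL,
                                     stdev_window = 3, seed = 1L,
                                     include_variability = TRUE) {
  yrs <- rcp_anomaly$year
  base <- hist_dit$value[length(hist_dit$value)]
  anom <- rcp_anomaly$value
  amo <- if (is.null(amo_projection)) rep(0, length(yrs))
  else cs_value(amo_projection, yrs)
  if (anyNA(amo))
    stop("oscillation series missing years: ",
         paste(yrs[is.na(amo)], collapse = ", "))

  vari <- rep(0, length(yrs))
  if (include_variability) {
    h <- hist_dit$value
    resid <- h - zoo::rollmean(h, stdev_window, fill = "extend")
    sd_roll <- zoo::rollapply(resid, stdev_window, sd, fill = "extend")
    sd_seq <- rep_len(sd_roll, length(yrs))
    set.seed(seed)
    vari <- rnorm(length(yrs), 0, sd_seq)
  }
  out <- climate_series(yrs, base + anom + vari + amo, label = "future DIT")
  attr(out, "components") <- data.frame(year = yrs, base = base,
                                        anomaly = anom,
                                        variability = vari, amo = amo)
  out
}

#' Synthetic warming-scenario anomaly series
#'
#' Stand-ins for ensemble-mean warming anomalies at four RCP-like
#' intensities, referenced to 0 in the first projection year: the low
#' scenario rises then stabilises mid-century (concave), the others rise
#' quasi-linearly to about +1.0, +1.8, +2.2 and +3.7 deg C by 2100
#' (CMIP5-like shelf-sea magnitudes).
#'
#' @param years projection years.
#' @param scenario one of "rcp26", "rcp45", "rcp65", "rcp85".
#' @return a [climate_series()] anomaly.
#' @export
rcp_anomaly_series <- function(years,
                               scenario = c("rcp26", "rcp45", "rcp65", "rcp85")) {
  scenario <- match.arg(scenario)
  u <- (years - years[1]) / (max(years) - years[1])
  v <- switch(scenario,
              rcp26 = 1.0 * (1 - (1 - u)^2) * (1 - 0.15 * u),  # stabilising
              rcp45 = 1.8 * u^1.1,
              rcp65 = 2.2 * u^1.2,
              rcp85 = 3.7 * u^1.3)
  climate_series(years, v - v[1], label = scenario)
}

#' Fishing/temperature scenario specification
#'
#' @param name scenario label.
#' @param f_by_group named vector of fishing mortalities (yr^-1) applied
#'   from `start_year` (e.g. status-quo or MSY values); groups absent keep
#'   their hindcast-end F.
#' @param temperature a [climate_series()] covering `start_year:end_year`,
#'   or `NULL` to hold temperature at the last hindcast value.
#' @param start_year,end_year projection window.
#' @param f_ramp optional maximum fractional change of F per year (e.g.
#'   0.15); `NULL` (default) applies the scenario F as a step change.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, f_by_group, temperature = NULL,
                          start_year, end_year, f_ramp = NULL) {
  stopifnot(end_year >= start_year)
  if (any(f_by_group < 0)) stop("F must be >= 0")
  structure(list(name = name, f_by_group = f_by_group,
                 temperature = temperature, start_year = start_year,
                 end_year = end_year, f_ramp = f_ramp),
            class = "scenario_spec")
}

#' Project a fitted model under a fishing/temperature scenario
#'
#' Continues the hindcast from its end state, applying the scenario's
#' fishing mortalities (step change by default, or ramped by at most
#' `f_ramp` per year) and temperature mode, and reports trajectories plus
#' cumulative biomass/catch summaries over the scenario groups.
#'
#' @param web,sol,arena model, baseline solution and (fitted) arena.
#' @param scenario a [scenario_spec()].
#' @param state0 biomass state at scenario start (default: the mass-balance
#'   baseline; normally the hindcast `final_state`).
#' @param f_start named vector of F in the year before the scenario (used
#'   for ramping and for groups not in `f_by_group`); default `sol$f0`.
#' @param pp_multiplier optional producer multiplier over the scenario
#'   years.
#' @param ... passed to [simulate_web()].
#' @return object of class `scenario_result`: the `ecosim_run`, plus
#'   `cumulative` (per-group summed biomass and catch in the final year and
#'   over the run) and the scenario.
#' @export
project_scenario <- function(web, sol, arena, scenario, state0 = NULL,
                             f_start = NULL, pp_multiplier = NULL, ...) {
  stopifnot(inherits(scenario, "scenario_spec"))
  yrs <- scenario$start_year:scenario$end_year
  ny <- length(yrs)
  full_f <- sol$f0
  if (!is.null(f_start)) full_f[group_index(web, names(f_start))] <- f_start
  f_start <- full_f
  fmat <- matrix(rep(f_start, each = ny), ny, n_groups(web),
                 dimnames = list(yrs, web$groups$name))
  tgt <- scenario$f_by_group
  idx <- group_index(web, names(tgt))
  if (is.null(scenario$f_ramp)) {
    fmat[, idx] <- rep(tgt, each = ny)
  } else {
    r <- scenario$f_ramp
    for (k in seq_along(tgt)) {
      f <- f_start[idx[k]]
      for (y in seq_len(ny)) {
        lo <- f * (1 - r); hi <- f * (1 + r)
        f <- min(max(tgt[k], lo), hi)
        fmat[y, idx[k]] <- f
      }
    }
  }
  temp <- if (is.null(scenario$temperature)) NULL
  else cs_value(scenario$temperature, yrs)
  if (!is.null(temp) && anyNA(temp))
    stop("scenario temperature does not cover ",
         paste(yrs[is.na(temp)], collapse = ", "))
  forcing <- forcing_set(yrs, temperature = temp, f_mort = fmat,
                         pp_multiplier = pp_multiplier)
  run <- simulate_web(web, sol, arena, forcing, state0 = state0, ...)
  groups <- names(tgt)
  cum <- data.frame(
    group = colnames(run$biomass),
    biomass_start = run$biomass[1, ],
    biomass_end = run$biomass[ny, ],
    catch_start = run$catch[1, ],
    catch_end = run$catch[ny, ],
    catch_total = colSums(run$catch),
    row.names = NULL)
  structure(list(run = run, cumulative = cum, scenario = scenario),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result:", x$scenario$name, "(",
      x$scenario$start_year, "-", x$scenario$end_year, ")\n")
  print(x$cumulative, digits = 4)
  invisible(x)
}

#' Percent decrease between two cumulative totals
#'
#' `round(100 * (initial - final) / initial)` - the arithmetic used to
#' report, e.g., a drop of cumulative biomass from 15.8 to 13.5 t km^-2 as
#' a 15% decrease (negative values indicate an increase).
#'
#' @param initial,final totals (initial > 0).
#' @return percent decrease, rounded to the nearest whole percent.
#' @export
cumulative_change <- function(initial, final) {
  if (any(initial <= 0)) stop("initial must be > 0")
  round(100 * (initial - final) / initial)
}
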