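#' Species thermal niche
#'
#' A thermal niche is a two-sided Gaussian response centred on the species'
#' optimum temperature: the consumption scaling factor is 1 exactly at
#' `t_opt` and declines as \eqn{\exp(-(T - t_{opt})^2 / 2\sigma^2)} with a
#' possibly different standard deviation below (`sigma_lower`) and above
#' (`sigma_upper`) the optimum, reflecting asymmetric thermal tolerance.
#'
#' @param t_opt optimum temperature, deg C.
#' @param sigma_lower,sigma_upper tolerance standard deviations (deg C > 0)
#'   for temperatures below / above the optimum.
#' @param t_min,t_max envelope limits, deg C (default `t_opt` minus/plus two
#'   standard deviations).
#' @param p10,p90 optional 10th/90th preferred-temperature percentiles.
#' @return object of class `thermal_niche`.
#' @export
thermal_niche <- function(t_opt, sigma_lower, sigma_upper = sigma_lower,
                          t_min = t_opt - 2 * sigma_lower,
                          t_max = t_opt + 2 * sigma_upper,
                          p10 = NA_real_, p90 = NA_real_) {
  stopifnot(is.finite(t_opt), sigma_lower > 0, sigma_upper > 0)
  if (!(t_min <= t_opt && t_opt <= t_max))
    stop("need t_min <= t_opt <= t_max")
  structure(list(t_opt = t_opt, sigma_lower = sigma_lower,
                 sigma_upper = sigma_upper, t_min = t_min, t_max = t_max,
                 p10 = p10, p90 = p90),
            class = "thermal_niche")
}

#' @export
print.thermal_niche <- function(x, ...) {
  cat(sprintf("thermal_niche: t_opt = %.2f C, sigma -/+ = %.3f/%.3f C, range [%.2f, %.2f]\n",
              x$t_opt, x$sigma_lower, x$sigma_upper, x$t_min, x$t_max))
  invisible(x)
}

#' Evaluate the thermal response scaling factor
#'
#' Returns the consumption scaling factor in (0, 1] for a temperature:
#' exactly 1 at the optimum and Gaussian-declining away from it, using the
#' lower-side standard deviation below the optimum and the upper-side one
#' at or above it. With `symmetric = TRUE` both sides use the mean of the
#' two sigmas (a sensitivity mode).
#'
#' @param niche a [thermal_niche()].
#' @param temperature numeric vector of temperatures, deg C.
#' @param symmetric use a single pooled sigma on both sides.
#' @return numeric vector of scaling factors in (0, 1].
#' @export
thermal_response <- function(niche, temperature, symmetric = FALSE) {
  stopifnot(inherits(niche, "thermal_niche"))
  if (any(!is.finite(temperature))) stop("non-finite temperature")
  if (symmetric) {
    s <- rep((niche$sigma_lower + niche$sigma_upper) / 2, length(temperature))
  } else {
    s <- ifelse(temperature < niche$t_opt, niche$sigma_lower, niche$sigma_upper)
  }
  exp(-((temperature - niche$t_opt)^2) / (2 * s^2))
}

#' Build a thermal niche from envelope temperatures
#'
#' The optimum is the mean of the 10th and 90th preferred-temperature
#' percentiles; the side standard deviations place the envelope limits
#' `k_sigma` standard deviations from the optimum (default 2, i.e. the
#' reported min/max are treated as ~2-sigma excursions). Degenerate
#' zero-width sides are given a floor width.
#'
#' @param t_min,p10,p90,t_max envelope temperatures, deg C, non-decreasing.
#' @param k_sigma number of standard deviations between optimum and
#'   envelope edge (default 2).
#' @param sigma_floor minimum side standard deviation, deg C (default 0.5).
#' @return a [thermal_niche()].
#' @export
build_niche <- function(t_min, p10, p90, t_max, k_sigma = 2,
                        sigma_floor = 0.5) {
  if (!(t_min <= p10 && p10 <= p90 && p90 <= t_max))
    stop("need t_min <= p10 <= p90 <= t_max")
  t_opt <- (p10 + p90) / 2
  sl <- max((t_opt - t_min) / k_sigma, sigma_floor)
  su <- max((t_max - t_opt) / k_sigma, sigma_floor)
  thermal_niche(t_opt, sl, su, t_min = t_min, t_max = t_max,
                p10 = p10, p90 = p90)
}

#' Aggregate thermal niches of co-occurring species
#'
#' Multi-species functional groups get envelope parameters equal to the
#' weighted geometric means of the member species' parameters, weights
#' being biomass or catch shares. Temperatures at or below zero are shifted
#' to a positive scale before log-averaging (offset 1 - min value) and
#' shifted back afterwards. The optimum and sigmas are then rebuilt with
#' [build_niche()].
#'
#' @param niches list of [thermal_niche()] objects.
#' @param weights non-negative weights, at least one positive.
#' @param k_sigma,sigma_floor passed to [build_niche()].
#' @return a [thermal_niche()].
#' @export
aggregate_niches <- function(niches, weights, k_sigma = 2, sigma_floor = 0.5) {
  stopifnot(length(niches) == length(weights), all(weights >= 0))
  if (sum(weights) <= 0) stop("all-zero weights")
  w <- weights / sum(weights)
  pars <- sapply(c("t_min", "p10", "p90", "t_max"), function(p) {
    x <- vapply(niches, function(nc) {
      v <- nc[[p]]
      if (is.na(v) && p %in% c("p10", "p90")) v <- nc$t_opt
      v
    }, numeric(1))
    off <- if (any(x <= 0)) 1 - min(x) else 0
    exp(sum(w * log(x + off))) - off
  })
  build_niche(pars[["t_min"]], pars[["p10"]], pars[["p90"]], pars[["t_max"]],
              k_sigma = k_sigma, sigma_floor = sigma_floor)
}

#' Shift a thermal niche by a constant offset
#'
#' Translates every envelope temperature by `delta` (default +1 deg C, the
#' adjustment used for juvenile pools assumed to occupy shallower, warmer
#' water); sigmas are unchanged, so the shifted response at T + delta
#' equals the original response at T.
#'
#' @param niche a [thermal_niche()].
#' @param delta temperature shift, deg C.
#' @return shifted [thermal_niche()].
#' @export
juvenile_offset <- function(niche, delta = 1) {
  stopifnot(inherits(niche, "thermal_niche"))
  thermal_niche(niche$t_opt + delta, niche$sigma_lower, niche$sigma_upper,
                t_min = niche$t_min + delta, t_max = niche$t_max + delta,
                p10 = niche$p10 + delta, p90 = niche$p90 + delta)
}

#' Wide plankton-type niche centred on the historical temperature mean
#'
#' Groups without usable tolerance data (phytoplankton, zooplankton) are
#' given an optimum equal to the mean of the supplied historical
#' temperature series with wide tolerances on both sides, so their
#' consumption is effectively insensitive to realistic temperature change.
#'
#' @param temperature historical temperature series (numeric, deg C).
#' @param sigma side standard deviation, deg C (default 10).
#' @return a [thermal_niche()].
#' @export
plankton_niche <- function(temperature, sigma = 10) {
  thermal_niche(mean(temperature), sigma, sigma)
}

niches_from_table <- function(df) {
  stopifnot(all(c("name", "t_min", "p10", "p90", "t_max") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (!is.null(df$sigma_lower) && !is.na(r$sigma_lower) &&
        !is.null(df$sigma_upper) && !is.na(r$sigma_upper)) {
      thermal_niche((r$p10 + r$p90) / 2, r$sigma_lower, r$sigma_upper,
                    t_min = r$t_min, t_max = r$t_max,
                    p10 = r$p10, p90 = r$p90)
    } else {
      build_niche(r$t_min, r$p10, r$p90, r$t_max)
    }
  })
  names(out) <- df$name
  out
}
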