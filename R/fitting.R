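#' Weighted log sum of squares between predicted and observed series
#'
#' The fitting objective: for every observed series (a group and a kind,
#' biomass or catch) the residuals are differences of natural logs between
#' observation and prediction in the overlapping years, squared, summed and
#' weighted by the series weight. Series with weight 0 are excluded.
#'
#' @param run an [simulate_web()] trajectory.
#' @param observed data.frame with columns `group`, `kind` ("biomass" or
#'   "catch"), `year`, `value` (> 0) and optionally `weight` (default 1).
#' @return the weighted sum of squares (single number).
#' @export
sum_of_squares <- function(run, observed) {
  stopifnot(inherits(run, "ecosim_run"))
  observed <- check_observed(observed)
  ss <- 0
  for (key in split(observed, list(observed$group, observed$kind), drop = TRUE)) {
    w <- key$weight[1]
    if (w == 0) next
    grp <- key$group[1]
    mat <- if (key$kind[1] == "biomass") run$biomass else run$catch
    if (!grp %in% colnames(mat)) stop("unknown group in observations: ", grp)
    idx <- match(key$year, run$years)
    if (all(is.na(idx)))
      stop("no overlapping years for series ", grp, "/", key$kind[1])
    keep <- !is.na(idx)
    pred <- mat[idx[keep], grp]
    obs <- key$value[keep]
    if (any(obs <= 0))
      stop("non-positive observed value in series ", grp, "/", key$kind[1])
    if (any(pred <= 0))
      stop("non-positive predicted value in series ", grp, "/", key$kind[1])
    ss <- ss + w * sum((log(obs) - log(pred))^2)
  }
  ss
}

check_observed <- function(observed) {
  stopifnot(is.data.frame(observed),
            all(c("group", "kind", "year", "value") %in% names(observed)))
  if (is.null(observed$weight)) observed$weight <- rep(1, nrow(observed))
  if (any(observed$weight < 0)) stop("weights must be >= 0")
  if (!all(observed$kind %in% c("biomass", "catch")))
    stop("kind must be 'biomass' or 'catch'")
  observed
}

#' Primary-production anomaly spline
#'
#' A positive multiplier on producer production, interpolated through
#' `n_points` knots evenly spaced over the fit window. Interpolation is a
#' monotone-safe cubic (Fritsch-Carlson Hermite) through the log values, so
#' the multiplier cannot overshoot between knots and stays positive.
#' Zero knots means a multiplier identically 1.
#'
#' @param values positive values at the knots (length = number of knots).
#' @param window two-element year range the knots span.
#' @return object of class `spline_anomaly`.
#' @export
spline_anomaly <- function(values = numeric(0), window = NULL) {
  n <- length(values)
  if (n > 0L) stopifnot(!is.null(window), all(values > 0))
  knots <- if (n == 0L) numeric(0)
  else if (n == 1L) mean(window)
  else seq(window[1], window[2], length.out = n)
  structure(list(n_points = n, knot_years = knots, values = values,
                 window = window),
            class = "spline_anomaly")
}

#' Evaluate a [spline_anomaly()] at a set of years
#' @param anomaly a [spline_anomaly()].
#' @param years numeric vector of years.
#' @return positive multiplier per year.
#' @export
anomaly_multiplier <- function(anomaly, years) {
  stopifnot(inherits(anomaly, "spline_anomaly"))
  n <- anomaly$n_points
  if (n == 0L) return(rep(1, length(years)))
  if (n == 1L) return(rep(anomaly$values, length(years)))
  f <- splinefun(anomaly$knot_years, log(anomaly$values), method = "monoH.FC")
  yrs <- pmin(pmax(years, min(anomaly$knot_years)), max(anomaly$knot_years))
  exp(f(yrs))
}

#' Akaike information criteria from a sum of squares
#'
#' For least-squares fits, \eqn{AIC = n \ln(SS/n) + 2k} and
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}, with `n` observations and `k`
#' estimated parameters.
#'
#' @param ss sum of squares (> 0).
#' @param n_obs number of observations.
#' @param k_params number of estimated parameters.
#' @return list with `aic` and `aicc` (`aicc` is `NA` when
#'   `n_obs <= k_params + 1`).
#' @export
information_criteria <- function(ss, n_obs, k_params) {
  if (ss <= 0) stop("ss must be > 0 (perfect fit is degenerate for AIC)")
  aic <- n_obs * log(ss / n_obs) + 2 * k_params
  aicc <- if (n_obs > k_params + 1)
    aic + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
  else NA_real_
  list(aic = aic, aicc = aicc)
}

#' Akaike weights of a candidate model set
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}; the weight of a model is the
#' probability that it is the best of the candidate set.
#'
#' @param aics numeric vector of AIC values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) == 0L) stop("empty AIC list")
  if (any(!is.finite(aics))) stop("non-finite AIC values")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

# simulate under candidate parameters: per-predator vulnerabilities v_by
# (named), an anomaly, and the fit forcing; search rates recalibrated so the
# candidate web still reproduces the mass-balance baseline
fit_simulate <- function(web, sol, forcing, v_by = NULL, anomaly = NULL,
                         steps_per_year = 12, producer_env = TRUE) {
  n <- n_groups(web)
  v <- web$vulnerability
  if (!is.null(v_by) && length(v_by) > 0L) {
    idx <- group_index(web, names(v_by))
    v[, idx] <- rep(pmax(v_by, 1 + 1e-10), each = n)
  }
  arena <- calibrate_arena(sol, v = v, d = web$handling)
  pp <- forcing$pp_multiplier
  if (!is.null(anomaly) && anomaly$n_points > 0L) {
    mult <- anomaly_multiplier(anomaly, forcing$years)
    pp <- if (is.null(pp)) mult else pp * mult
  }
  f2 <- forcing
  f2$pp_multiplier <- pp
  simulate_web(web, sol, arena, f2, steps_per_year = steps_per_year,
               producer_env = producer_env)
}

fit_objective <- function(theta, web, sol, forcing, observed, predators,
                          n_spline, window, steps_per_year, producer_env) {
  nv <- length(predators)
  v_by <- if (nv > 0L) setNames(1 + exp(theta[seq_len(nv)]), predators)
  anom <- if (n_spline > 0L)
    spline_anomaly(pmax(exp(theta[nv + seq_len(n_spline)]), 1e-8), window)
  run <- tryCatch(
    fit_simulate(web, sol, forcing, v_by, anom, steps_per_year, producer_env),
    error = function(e) NULL)
  if (is.null(run)) return(1e10)
  ss <- tryCatch(sum_of_squares(run, observed), error = function(e) 1e10)
  if (!is.finite(ss)) 1e10 else ss
}

optimize_config <- function(web, sol, forcing, observed, predators, n_spline,
                            window, control, steps_per_year, producer_env,
                            warm = list()) {
  np <- length(predators) + n_spline
  obj <- function(th) fit_objective(th, web, sol, forcing, observed,
                                    predators, n_spline, window,
                                    steps_per_year, producer_env)
  if (np == 0L)
    return(list(theta = numeric(0), ss = obj(numeric(0)), converged = TRUE))

  if (np == 1L) {
    # bracket the minimum on a coarse grid, then golden-section refine
    grid <- seq(-3.5, 3.5, by = 0.5)
    cand <- c(grid, unlist(warm))
    vals <- vapply(cand, obj, numeric(1))
    t0 <- cand[which.min(vals)]
    o <- optimize(obj, interval = c(t0 - 0.75, t0 + 0.75), tol = 1e-6)
    if (min(vals) < o$objective) o <- list(minimum = t0, objective = min(vals))
    return(list(theta = o$minimum, ss = o$objective, converged = TRUE))
  }

  starts <- c(warm, list(rep(0, np)))  # warm starts, then v = 2 / mult = 1
  while (length(starts) < control$n_starts)
    starts <- c(starts, list(rnorm(np, 0, control$jitter)))
  best <- NULL
  for (th0 in starts) {
    fit <- optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = control$maxit, reltol = control$reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(theta = best$par, ss = best$value, converged = best$convergence == 0L)
}

#' Stepwise AIC search over vulnerabilities and anomaly spline points
#'
#' Replays the automated stepwise fitting strategy: candidate
#' configurations estimate the vulnerabilities of 0 to `max_v` predators
#' ("by predator": one value shared by all prey links of that predator) and
#' 0 to `max_spline` knots of a primary-production anomaly spline, each
#' configuration minimising the weighted log sum of squares by local search
#' over transformed parameters (v = 1 + exp(theta), so fitted
#' vulnerabilities stay in (1, Inf); knot values exp(theta) > 0). The set
#' always includes the baseline row (no fishing variation, k = 0) and a
#' fishing-only row (k = 0). Predators enter in greedy order of their
#' single-predator SS reduction unless `exhaustive = TRUE` (feasible for
#' small webs). Results are ranked by AIC and given Akaike weights.
#'
#' @param web,sol,forcing model, baseline solution and fit-window forcing
#'   (temperature and fishing series; the anomaly is added internally).
#' @param observed observation table (see [sum_of_squares()]).
#' @param max_v maximum number of predators whose vulnerability is
#'   estimated.
#' @param max_spline maximum number of anomaly spline points.
#' @param predators candidate predators (default: all consumers).
#' @param exhaustive try all predator subsets up to size `max_v` instead of
#'   the greedy ordering (only sensible for <= 8 predators).
#' @param control list: `maxit` (default 400), `reltol` (1e-8), `n_starts`
#'   (3), `jitter` (0.5), `seed` (1) for the extra randomised starts.
#' @param steps_per_year,producer_env passed to [simulate_web()].
#' @return object of class `stepwise_fit`: `results` (list of fit results),
#'   `table` (ranked summary data.frame), `best` (best-AIC result).
#' @export
stepwise_fit <- function(web, sol, forcing, observed, max_v = 2,
                         max_spline = 3, predators = NULL,
                         exhaustive = FALSE, control = list(),
                         steps_per_year = 12, producer_env = TRUE) {
  observed <- check_observed(observed)
  control <- utils::modifyList(
    list(maxit = 400, reltol = 1e-8, n_starts = 3, jitter = 0.5, seed = 1L),
    control)
  set.seed(control$seed)
  window <- range(forcing$years)
  g <- web$groups
  if (is.null(predators))
    predators <- g$name[!g$is_producer & !g$is_detritus & g$qb > 0]
  n_obs <- sum(observed$weight > 0 &
                 observed$year >= window[1] & observed$year <= window[2])

  results <- list()
  add_result <- function(name, preds, n_spline, opt, f_used) {
    nv <- length(preds)
    v_by <- if (nv > 0L) setNames(1 + exp(opt$theta[seq_len(nv)]), preds)
    anom <- if (n_spline > 0L)
      spline_anomaly(pmax(exp(opt$theta[nv + seq_len(n_spline)]), 1e-8), window)
    else spline_anomaly()
    k <- nv + n_spline
    ic <- information_criteria(max(opt$ss, 1e-12), n_obs, k)
    results[[length(results) + 1L]] <<- list(
      name = name, ss = opt$ss, n_obs = n_obs, k_params = k,
      n_v = nv, n_spline = n_spline, aic = ic$aic, aicc = ic$aicc,
      v_by_predator = v_by, anomaly = anom,
      anomaly_series = anomaly_multiplier(anom, forcing$years),
      converged = opt$converged, forcing_used = f_used)
  }

  # baseline: fishing held constant at the mass-balance F, nothing estimated
  f_base <- forcing
  f_base$f_mort <- NULL
  ss_base <- sum_of_squares(
    fit_simulate(web, sol, f_base, steps_per_year = steps_per_year,
                 producer_env = producer_env), observed)
  add_result("baseline", character(0), 0L,
             list(theta = numeric(0), ss = ss_base, converged = TRUE), "baseline")
  # fishing only
  ss_fish <- sum_of_squares(
    fit_simulate(web, sol, forcing, steps_per_year = steps_per_year,
                 producer_env = producer_env), observed)
  add_result("fishing", character(0), 0L,
             list(theta = numeric(0), ss = ss_fish, converged = TRUE), "fishing")

  run_cfg <- function(preds, nsp, warm = list())
    optimize_config(web, sol, forcing, observed, preds, nsp, window,
                    control, steps_per_year, producer_env, warm = warm)

  # re-space spline thetas when a knot is added (warm-start helper)
  pad_spline <- function(th_s, new_n) {
    k <- length(th_s)
    if (new_n == 0L) return(numeric(0))
    if (k == 0L) return(rep(0, new_n))
    if (k == 1L) return(rep(th_s, new_n))
    approx(seq(0, 1, length.out = k), th_s,
           xout = seq(0, 1, length.out = new_n), rule = 2)$y
  }

  # greedy predator ordering by single-predator SS reduction
  scan <- lapply(predators, function(p) run_cfg(p, 0L))
  names(scan) <- predators
  ord <- order(vapply(scan, `[[`, numeric(1), "ss"))
  greedy <- predators[ord]

  subsets <- if (exhaustive) {
    unlist(lapply(seq_len(min(max_v, length(predators))), function(k)
      utils::combn(predators, k, simplify = FALSE)), recursive = FALSE)
  } else {
    lapply(seq_len(min(max_v, length(predators))), function(k) greedy[seq_len(k)])
  }

  # cache of optimised configurations for warm starts: key "<preds>|<nsp>"
  cache <- list()
  ckey <- function(preds, nsp) paste(paste(preds, collapse = ","), nsp, sep = "|")
  run_warm <- function(preds, nsp) {
    nv <- length(preds)
    warm <- list()
    prev_s <- cache[[ckey(preds, nsp - 1L)]]     # one fewer spline knot
    if (!is.null(prev_s))
      warm <- c(warm, list(c(prev_s$theta[seq_len(nv)],
                             pad_spline(prev_s$theta[-seq_len(nv)], nsp))))
    if (nv > 0L) {                               # one fewer predator
      prev_v <- cache[[ckey(preds[-nv], nsp)]]
      if (!is.null(prev_v)) {
        nv0 <- nv - 1L
        seed_v <- scan[[preds[nv]]]$theta
        head_v <- if (nv0 > 0L) prev_v$theta[seq_len(nv0)] else numeric(0)
        tail_s <- if (nv0 > 0L) prev_v$theta[-seq_len(nv0)] else prev_v$theta
        warm <- c(warm, list(c(head_v, seed_v, tail_s)),
                  # neutral v = 2 for the added predator reproduces the
                  # smaller configuration exactly (nesting guarantee)
                  list(c(head_v, 0, tail_s)))
      }
    }
    opt <- run_cfg(preds, nsp, warm = warm)
    cache[[ckey(preds, nsp)]] <<- opt
    opt
  }
  cache[[ckey(character(0), 0L)]] <- list(theta = numeric(0), ss = ss_fish)
  for (p in predators) cache[[ckey(p, 0L)]] <- scan[[p]]

  for (nsp in seq_len(max_spline))
    add_result(sprintf("fishing + %d PP_anomaly", nsp), character(0), nsp,
               run_warm(character(0), nsp), "fishing")
  for (ps in subsets) {
    nv <- length(ps)
    opt <- if (nv == 1L && !is.null(cache[[ckey(ps, 0L)]]))
      cache[[ckey(ps, 0L)]] else run_warm(ps, 0L)
    cache[[ckey(ps, 0L)]] <- opt
    add_result(sprintf("fishing + %d Vs", nv), ps, 0L, opt, "fishing")
    for (nsp in seq_len(max_spline))
      add_result(sprintf("fishing + %d Vs + %d PP_anomaly", nv, nsp),
                 ps, nsp, run_warm(ps, nsp), "fishing")
  }

  aics <- vapply(results, `[[`, numeric(1), "aic")
  w <- akaike_weights(aics)
  for (i in seq_along(results)) results[[i]]$akaike_weight <- w[i]
  ord2 <- order(aics)
  results <- results[ord2]

  tab <- data.frame(
    name = vapply(results, `[[`, character(1), "name"),
    k_params = vapply(results, `[[`, numeric(1), "k_params"),
    ss = vapply(results, `[[`, numeric(1), "ss"),
    ss_reduction_pct = round(100 * (ss_base - vapply(results, `[[`, numeric(1), "ss")) / ss_base),
    aic = vapply(results, `[[`, numeric(1), "aic"),
    akaike_weight = vapply(results, `[[`, numeric(1), "akaike_weight"),
    converged = vapply(results, `[[`, logical(1), "converged"),
    row.names = NULL)

  structure(list(results = results, table = tab, best = results[[1]],
                 window = window),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("stepwise_fit over", nrow(x$table), "configurations; best:",
      x$best$name, sprintf("(SS %.4g, AIC %.2f)\n", x$best$ss, x$best$aic))
  print(x$table, digits = 4)
  invisible(x)
}
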