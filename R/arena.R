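#' Foraging-arena consumption rate for one predator-prey link
#'
#' Consumption follows the foraging-arena form in which prey exchange
#' between vulnerable and invulnerable pools at rate `v` and predators
#' remove vulnerable prey with effective search rate `a`, moderated by
#' relative feeding times, a mediation multiplier, a handling-time limit
#' and a time-varying environmental (thermal) scaling:
#' \deqn{Q = \frac{a v B_i P_j T_i T_j M}{v + v T_i M + a M P_j T_j / D} \times f_{env}}
#' The handling-time term enters the denominator only, so `d = Inf` removes
#' the handling limit. `literal_pool = TRUE` substitutes the prey-side pool
#' for the predator pool in the denominator's saturation term (an
#' alternative printed form of the equation).
#'
#' @param a effective search rate ((t km^-2)^-1 yr^-1).
#' @param v vulnerability exchange rate, >= 1 (2 is the neutral default;
#'   > 2 behaves top-down, 1-2 bottom-up).
#' @param b_prey,p_pred prey and predator biomass (t km^-2).
#' @param t_prey,t_pred relative feeding times (default 1).
#' @param m mediation multiplier (default 1).
#' @param d handling time (yr; `Inf` = no handling limit).
#' @param env_scale environmental scaling factor in [0, 1].
#' @param literal_pool use the prey biomass in the denominator saturation
#'   term instead of the predator pool.
#' @return consumption rate, t km^-2 yr^-1.
#' @export
consumption_rate <- function(a, v, b_prey, p_pred, t_prey = 1, t_pred = 1,
                             m = 1, d = Inf, env_scale = 1,
                             literal_pool = FALSE) {
  if (any(c(a, b_prey, p_pred, t_prey, t_pred, m, d) < 0))
    stop("negative arena inputs")
  if (any(v < 1)) stop("vulnerability must be >= 1")
  if (any(env_scale < 0 | env_scale > 1)) stop("env_scale must be in [0, 1]")
  if (a == 0 || env_scale == 0) return(0)
  pool <- if (literal_pool) b_prey else p_pred
  hand <- if (is.infinite(d)) 0 else a * m * pool * t_pred / d
  (a * v * b_prey * p_pred * t_prey * t_pred * m) /
    (v + v * t_prey * m + hand) * env_scale
}

#' Arena parameters for a food web
#'
#' Container for the per-link foraging-arena constants: search rates `a`,
#' vulnerabilities `v` (prey x predator matrices), per-predator handling
#' times `d` and the mediation matrix `m` (fixed at 1 unless supplied).
#'
#' @param a,v prey x predator matrices.
#' @param d per-predator handling times (default 1, the standard
#'   predator-saturation term; `Inf` removes the saturation entirely, in
#'   which case the vulnerability cancels out of the consumption equation
#'   and every link behaves as Lotka-Volterra).
#' @param m mediation matrix (default all 1).
#' @return object of class `arena_params`.
#' @export
arena_params <- function(a, v, d = rep(1, ncol(a)), m = NULL) {
  stopifnot(all(dim(a) == dim(v)), length(d) == ncol(a))
  if (is.null(m)) m <- matrix(1, nrow(a), ncol(a))
  if (any(a < 0)) stop("search rates must be >= 0")
  if (any(v < 1)) stop("vulnerabilities must be >= 1")
  structure(list(a = a, v = v, d = d, m = m), class = "arena_params")
}

#' Calibrate search rates to reproduce the mass-balance baseline
#'
#' The search rates are the free constants of the foraging-arena equation;
#' they are solved link by link in closed form so that, at the baseline
#' state (all feeding times and mediation at 1, environmental scaling 1),
#' the consumption of every link equals the baseline consumption q0 from
#' the mass balance:
#' \deqn{a = \frac{2 v Q_0}{P_0 (v B_0 - Q_0 / D)}}
#' A link is infeasible when the vulnerable-prey flux cannot supply the
#' baseline consumption (denominator <= 0); the error reports the minimum
#' feasible vulnerability for the link.
#'
#' @param sol an [balance_model()] solution.
#' @param v vulnerability matrix (defaults to the web's, else 2).
#' @param d per-predator handling times (default 1).
#' @param m mediation matrix (default 1).
#' @return an [arena_params()] object whose baseline consumption
#'   reproduces `sol$q0` to ~1e-10 relative.
#' @export
calibrate_arena <- function(sol, v = NULL, d = NULL, m = NULL) {
  stopifnot(inherits(sol, "ecopath_solution"))
  q0 <- sol$q0
  n <- nrow(q0)
  if (is.null(v)) v <- matrix(2, n, n, dimnames = dimnames(q0))
  if (is.null(d)) d <- rep(1, n)
  B0 <- sol$biomass
  a <- matrix(0, n, n, dimnames = dimnames(q0))
  for (j in seq_len(n)) {
    dj <- d[j]
    for (i in seq_len(n)) {
      if (q0[i, j] <= 0) next
      hand <- if (is.infinite(dj)) 0 else q0[i, j] / dj
      den <- B0[j] * (v[i, j] * B0[i] - hand)
      if (den <= 0) {
        vmin <- hand / B0[i]
        stop(sprintf(
          "infeasible link %s -> %s: baseline consumption exceeds vulnerable flux; needs v > %.4g",
          rownames(q0)[i], colnames(q0)[j], vmin))
      }
      a[i, j] <- 2 * v[i, j] * q0[i, j] / den
    }
  }
  arena_params(a = a, v = v, d = d, m = m)
}

#' Baseline consumption implied by arena parameters
#'
#' Evaluates the foraging-arena equation for every link at a given state
#' (feeding times 1, environment 1 by default); used to verify calibration
#' and inside the dynamic model.
#'
#' @param arena an [arena_params()].
#' @param biomass named biomass vector.
#' @param env_scale per-predator environmental scaling (default 1).
#' @param t_rel per-group relative feeding time (default 1).
#' @return prey x predator consumption matrix, t km^-2 yr^-1.
#' @export
arena_consumption <- function(arena, biomass, env_scale = NULL, t_rel = NULL) {
  n <- length(biomass)
  if (is.null(env_scale)) env_scale <- rep(1, n)
  if (is.null(t_rel)) t_rel <- rep(1, n)
  q <- matrix(0, n, n, dimnames = dimnames(arena$a))
  for (j in seq_len(n)) {
    dj <- arena$d[j]
    for (i in seq_len(n)) {
      if (arena$a[i, j] == 0) next
      q[i, j] <- consumption_rate(arena$a[i, j], arena$v[i, j],
                                  biomass[i], biomass[j],
                                  t_prey = t_rel[i], t_pred = t_rel[j],
                                  m = arena$m[i, j], d = dj,
                                  env_scale = env_scale[j])
    }
  }
  q
}
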