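#' Pedigree table of input confidence intervals
#'
#' One row per group with fractional half-widths (CVs) for the basic
#' mass-balance inputs. A fixed-CV mode (the classic "10% on everything")
#' is built with `pedigree_fixed()`. The production/biomass CV is capped at
#' 0.1 by default: wider P/B intervals interact multiplicatively with the
#' biomass interval and inflate the envelope disproportionately.
#'
#' @param group group names.
#' @param cv_b,cv_pb,cv_qb,cv_ee fractional half-widths in [0, 0.8].
#' @param cap_pb cap applied to `cv_pb` (default 0.1).
#' @return data.frame of class `pedigree`.
#' @export
pedigree <- function(group, cv_b = 0.1, cv_pb = 0.1, cv_qb = 0.1,
                     cv_ee = 0.1, cap_pb = 0.1) {
  df <- data.frame(group = group, cv_b = cv_b, cv_pb = cv_pb,
                   cv_qb = cv_qb, cv_ee = cv_ee)
  cvs <- as.matrix(df[, -1])
  if (any(cvs < 0 | cvs > 0.8)) stop("CVs must lie in [0, 0.8]")
  df$cv_pb <- pmin(df$cv_pb, cap_pb)
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @rdname pedigree
#' @param web a [food_web()] (fixed mode builds one row per group).
#' @param cv single fractional half-width applied to every input.
#' @export
pedigree_fixed <- function(web, cv = 0.1) {
  pedigree(web$groups$name, cv_b = cv, cv_pb = cv, cv_qb = cv, cv_ee = cv,
           cap_pb = max(cv, 0.1))
}

#' Monte Carlo propagation of mass-balance input uncertainty
#'
#' Each trial perturbs every group's supplied basic inputs (B, P/B, Q/B,
#' EE) by independent uniform draws within +/- CV of the base value,
#' re-solves the mass balance, rejects the trial if the perturbed web is
#' unbalanced (any EE outside [0, 1] or a non-positive solved biomass),
#' recalibrates the search rates on the accepted baseline with the fitted
#' vulnerabilities held fixed, re-runs the simulation, and accumulates the
#' trajectories until `n_trials` have been accepted. The envelope is the
#' empirical 5th/95th percentile (and median) per group, kind and year.
#'
#' @param web,sol,arena,forcing as for [simulate_web()]; `arena` supplies
#'   the (fitted) vulnerabilities.
#' @param ped a [pedigree()] table.
#' @param n_trials accepted trials required (default 200).
#' @param seed RNG seed.
#' @param max_draw_factor abort if fewer than 1% of `max_draw_factor *
#'   n_trials` draws are accepted.
#' @param ... passed to [simulate_web()].
#' @return object of class `mc_envelope`: arrays `p5`, `p50`, `p95` (year x
#'   group, for biomass and catch), `n_accepted`, `n_drawn`, `draws`
#'   (matrix of sampled inputs, for auditing).
#' @export
monte_carlo <- function(web, sol, arena, forcing, ped, n_trials = 200,
                        seed = 1L, max_draw_factor = 50, ...) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(seed)
  g <- web$groups
  n <- nrow(g)
  idx <- match(g$name, ped$group)
  if (anyNA(idx)) stop("pedigree missing groups: ",
                       paste(g$name[is.na(idx)], collapse = ", "))
  ped <- ped[idx, ]
  ny <- length(forcing$years)

  acc_b <- array(NA_real_, c(n_trials, ny, n))
  acc_c <- array(NA_real_, c(n_trials, ny, n))
  draws <- matrix(NA_real_, 0, 4)
  accepted <- 0L
  drawn <- 0L
  while (accepted < n_trials) {
    if (drawn >= max_draw_factor * n_trials && accepted < drawn * 0.01)
      stop("Monte Carlo acceptance rate below 1% after ", drawn, " draws")
    drawn <- drawn + 1L
    w2 <- web
    u <- matrix(runif(4 * n, -1, 1), n, 4)
    pert <- function(x, cv, col) x * (1 + u[, col] * cv)
    w2$groups$biomass <- pert(g$biomass, ped$cv_b, 1)
    w2$groups$pb <- pert(g$pb, ped$cv_pb, 2)
    w2$groups$qb <- pert(g$qb, ped$cv_qb, 3)
    w2$groups$ee <- pert(g$ee, ped$cv_ee, 4)
    sol2 <- tryCatch(balance_model(w2), error = function(e) NULL)
    if (is.null(sol2) || !sol2$balanced || any(sol2$ee < 0, na.rm = TRUE))
      next
    arena2 <- tryCatch(calibrate_arena(sol2, v = arena$v, d = arena$d,
                                       m = arena$m),
                       error = function(e) NULL)
    if (is.null(arena2)) next
    run <- tryCatch(simulate_web(w2, sol2, arena2, forcing, ...),
                    error = function(e) NULL)
    if (is.null(run)) next
    accepted <- accepted + 1L
    acc_b[accepted, , ] <- run$biomass
    acc_c[accepted, , ] <- run$catch
    draws <- rbind(draws, cbind(w2$groups$biomass / g$biomass,
                                w2$groups$pb / g$pb,
                                w2$groups$qb / g$qb,
                                w2$groups$ee / g$ee))
  }

  qn <- function(arr, p) {
    out <- apply(arr, c(2, 3), quantile, probs = p, na.rm = TRUE)
    dimnames(out) <- list(forcing$years, g$name)
    out
  }
  structure(list(
    biomass = list(p5 = qn(acc_b, 0.05), p50 = qn(acc_b, 0.5),
                   p95 = qn(acc_b, 0.95)),
    catch = list(p5 = qn(acc_c, 0.05), p50 = qn(acc_c, 0.5),
                 p95 = qn(acc_c, 0.95)),
    n_accepted = accepted, n_drawn = drawn, draws = draws),
    class = "mc_envelope")
}

#' @export
print.mc_envelope <- function(x, ...) {
  cat("mc_envelope:", x$n_accepted, "accepted of", x$n_drawn, "trials\n")
  invisible(x)
}

#' Chronological fit/hold-out split of an observation set
#'
#' Named schemes follow the three validation subsets used for hindcast
#' skill assessment on a 29-year window: A = 22 fit + 7 hold-out years,
#' B = 24 + 5, C = 26 + 3, always splitting chronologically (the hold-out
#' set is the final block). An explicit integer gives the hold-out length
#' directly.
#'
#' @param observed observation table (see [sum_of_squares()]).
#' @param scheme "A", "B", "C", or a number of hold-out years.
#' @return list with `fit` and `holdout` observation tables (disjoint,
#'   union = input) and `split_year` (first hold-out year).
#' @export
validation_split <- function(observed, scheme = c("A", "B", "C")) {
  observed <- check_observed(observed)
  yrs <- sort(unique(observed$year))
  span <- length(yrs)
  if (is.character(scheme)) {
    scheme <- match.arg(scheme)
    if (span < 29)
      stop("named schemes need a series span of >= 29 years (have ", span, ")")
    h <- c(A = 7L, B = 5L, C = 3L)[[scheme]]
  } else {
    h <- as.integer(scheme)
    if (h <= 0 || h >= span) stop("hold-out length must be in (0, span)")
  }
  hold_years <- yrs[(span - h + 1L):span]
  list(fit = observed[!observed$year %in% hold_years, , drop = FALSE],
       holdout = observed[observed$year %in% hold_years, , drop = FALSE],
       split_year = hold_years[1])
}

#' Root-mean-square deviation between predicted and observed series
#'
#' Computed on the natural (untransformed) scale per series over the given
#' years, plus a pooled value over all residuals.
#'
#' @param run an [simulate_web()] trajectory.
#' @param observed observation table.
#' @param years years to score (default: all observed years).
#' @return data.frame with one row per series (`group`, `kind`, `rmsd`,
#'   `n`) plus attribute `pooled`.
#' @export
rmsd <- function(run, observed, years = NULL) {
  observed <- check_observed(observed)
  if (!is.null(years)) observed <- observed[observed$year %in% years, ]
  if (nrow(observed) == 0L) stop("no overlapping years to score")
  res <- list()
  all_sq <- numeric(0)
  for (key in split(observed, list(observed$group, observed$kind), drop = TRUE)) {
    grp <- key$group[1]; kind <- key$kind[1]
    mat <- if (kind == "biomass") run$biomass else run$catch
    idx <- match(key$year, run$years)
    keep <- !is.na(idx)
    if (!any(keep)) stop("no overlap for series ", grp, "/", kind)
    sq <- (mat[idx[keep], grp] - key$value[keep])^2
    res[[length(res) + 1L]] <- data.frame(
      group = grp, kind = kind, rmsd = sqrt(mean(sq)), n = sum(keep))
    all_sq <- c(all_sq, sq)
  }
  out <- do.call(rbind, res)
  attr(out, "pooled") <- sqrt(mean(all_sq))
  out
}
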