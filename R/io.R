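#' Read a food-web model directory
#'
#' A model directory holds `groups.csv` (columns name, is_producer,
#' is_detritus, biomass, pb, qb, ee, catch, stanza_partner; empty cells =
#' missing), `diet.csv` (square matrix, prey rows x predator columns, first
#' column the prey names), optionally `thermal.csv` (name, t_min, p10, p90,
#' t_max and optionally sigma_lower, sigma_upper which override the built
#' sigmas), optionally `vulnerability.csv`, and optionally `model.yaml`
#' with config entries (assimilation, stanza_rate, producer_cap, tol). All
#' tables are UTF-8 comma-delimited.
#'
#' @param dir model directory path.
#' @return a [food_web()].
#' @export
read_food_web <- function(dir) {
  path <- function(f) file.path(dir, f)
  if (!file.exists(path("groups.csv"))) stop("no groups.csv in ", dir)
  groups <- read.csv(path("groups.csv"), stringsAsFactors = FALSE)
  diet_raw <- read.csv(path("diet.csv"), check.names = FALSE,
                       stringsAsFactors = FALSE)
  diet <- as.matrix(diet_raw[, -1, drop = FALSE])
  rownames(diet) <- diet_raw[[1]]
  thermal <- if (file.exists(path("thermal.csv")))
    read.csv(path("thermal.csv"), stringsAsFactors = FALSE)
  vul <- if (file.exists(path("vulnerability.csv"))) {
    vr <- read.csv(path("vulnerability.csv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
    m <- as.matrix(vr[, -1, drop = FALSE]); rownames(m) <- vr[[1]]; m
  }
  config <- if (file.exists(path("model.yaml")))
    yaml::read_yaml(path("model.yaml")) else list()
  food_web(groups, diet, thermal = thermal, vulnerability = vul,
           config = config)
}

#' Write a food-web model directory
#'
#' Inverse of [read_food_web()]; writes `groups.csv`, `diet.csv`,
#' `thermal.csv` (if envelopes are present), `vulnerability.csv` and
#' `model.yaml`.
#'
#' @param web a [food_web()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_food_web <- function(web, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(web$groups, file.path(dir, "groups.csv"), row.names = FALSE,
            na = "")
  dm <- data.frame(name = rownames(web$diet), web$diet, check.names = FALSE)
  write.csv(dm, file.path(dir, "diet.csv"), row.names = FALSE)
  if (!is.null(web$thermal)) {
    th <- do.call(rbind, lapply(names(web$thermal), function(nm) {
      nc <- web$thermal[[nm]]
      # niches built without percentiles store the optimum in p10 = p90
      data.frame(name = nm, t_min = nc$t_min,
                 p10 = ifelse(is.na(nc$p10), nc$t_opt, nc$p10),
                 p90 = ifelse(is.na(nc$p90), nc$t_opt, nc$p90),
                 t_max = nc$t_max, sigma_lower = nc$sigma_lower,
                 sigma_upper = nc$sigma_upper)
    }))
    write.csv(th, file.path(dir, "thermal.csv"), row.names = FALSE, na = "")
  }
  vm <- data.frame(name = rownames(web$vulnerability), web$vulnerability,
                   check.names = FALSE)
  write.csv(vm, file.path(dir, "vulnerability.csv"), row.names = FALSE)
  cfg <- web$config
  cfg$handling <- as.list(web$handling)
  yaml::write_yaml(cfg, file.path(dir, "model.yaml"))
  invisible(dir)
}

#' Read an observation table (`group,kind,year,value,weight`)
#' @param path CSV file path.
#' @return validated observation data.frame.
#' @export
read_observed <- function(path) check_observed(read.csv(path))

#' Read an annual series CSV (`year,value`) as a [climate_series()]
#' @param path CSV file path.
#' @param label series label (defaults to the file name).
#' @export
read_climate_csv <- function(path, label = basename(path)) {
  df <- read.csv(path)
  climate_series(df$year, df$value, label = label)
}

#' Fit report in the style of a stepwise-fitting comparison table
#'
#' One row per candidate configuration: name, parameters estimated, SS,
#' percent SS reduction relative to the baseline row, AIC and Akaike
#' weight, ranked by AIC.
#'
#' @param fit a [stepwise_fit()] result.
#' @param path optional CSV output path.
#' @return the report data.frame.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "stepwise_fit"))
  tab <- fit$table
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}

#' Validation report: RMSD per series across hold-out schemes
#'
#' @param runs named list of trajectories (one per scheme, e.g. A/B/C).
#' @param holdouts named list of hold-out observation tables (same names).
#' @param path optional CSV output path.
#' @return data.frame with scheme, group, kind, rmsd and a pooled row.
#' @export
rmsd_report <- function(runs, holdouts, path = NULL) {
  stopifnot(identical(names(runs), names(holdouts)))
  out <- do.call(rbind, lapply(names(runs), function(s) {
    r <- rmsd(runs[[s]], holdouts[[s]])
    rbind(data.frame(scheme = s, r),
          data.frame(scheme = s, group = "(pooled)", kind = "all",
                     rmsd = attr(r, "pooled"), n = sum(r$n)))
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Cumulative biomass/catch change summary across scenarios
#'
#' Sums biomass and catch over a set of groups in the first and last
#' projected year of each scenario and reports the rounded percent
#' decrease, the arithmetic used for end-of-century cumulative summaries.
#'
#' @param results named list of [project_scenario()] results.
#' @param groups groups to accumulate over (default: all).
#' @param path optional CSV output path.
#' @return data.frame per scenario with cumulative start/end biomass and
#'   catch and percent decreases.
#' @export
cumulative_report <- function(results, groups = NULL, path = NULL) {
  out <- do.call(rbind, lapply(names(results), function(s) {
    cum <- results[[s]]$cumulative
    if (!is.null(groups)) cum <- cum[cum$group %in% groups, ]
    data.frame(scenario = s,
               biomass_start = sum(cum$biomass_start),
               biomass_end = sum(cum$biomass_end),
               biomass_decrease_pct = cumulative_change(
                 sum(cum$biomass_start), sum(cum$biomass_end)),
               catch_start = sum(cum$catch_start),
               catch_end = sum(cum$catch_end),
               catch_decrease_pct = cumulative_change(
                 sum(cum$catch_start), sum(cum$catch_end)))
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Run the full synthetic pipeline and write all stage outputs
#'
#' Generates a synthetic system from one seed, balances it, fits the
#' stepwise candidate set, runs the Monte Carlo envelope on the best fit,
#' scores the A/B/C hold-out splits, projects a warming-vs-constant
#' temperature scenario pair, and writes every stage's table plus a JSON
#' manifest (seed, options, package version) to `out_dir`. All randomness
#' flows from `seed`; given the same seed and options the outputs are
#' identical.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_trials Monte Carlo trials (default 200).
#' @param max_v,max_spline stepwise search bounds.
#' @param noise_cv observation noise CV.
#' @return invisibly, a list with all intermediate objects.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_trials = 200, max_v = 2,
                         max_spline = 3, noise_cv = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(seed = seed, noise_cv = noise_cv)
  sim <- make_observations(spec)
  write_food_web(sim$web, file.path(out_dir, "model"))
  write.csv(sim$observed, file.path(out_dir, "observed.csv"),
            row.names = FALSE)

  fit <- stepwise_fit(sim$web, sim$sol, sim$forcing, sim$observed,
                      max_v = max_v, max_spline = max_spline,
                      control = list(seed = seed))
  fit_report(fit, file.path(out_dir, "fit_report.csv"))

  arena_best <- best_fit_arena(sim$web, sim$sol, fit$best)
  ped <- pedigree_fixed(sim$web, cv = 0.1)
  env <- monte_carlo(sim$web, sim$sol, arena_best, sim$forcing, ped,
                     n_trials = n_trials, seed = seed)

  schemes <- c("A", "B", "C")
  runs <- list(); holds <- list()
  for (s in schemes) {
    sp <- validation_split(sim$observed, s)
    fw <- sim$forcing
    keep <- fw$years < sp$split_year
    ffit <- forcing_set(fw$years[keep],
                        temperature = fw$temperature[keep],
                        f_mort = fw$f_mort[keep, , drop = FALSE])
    f2 <- stepwise_fit(sim$web, sim$sol, ffit, sp$fit, max_v = max_v,
                       max_spline = max_spline,
                       control = list(seed = seed))
    runs[[s]] <- refit_run(sim$web, sim$sol, sim$forcing, f2$best)
    holds[[s]] <- sp$holdout
  }
  rmsd_report(runs, holds, file.path(out_dir, "rmsd_report.csv"))

  hind <- refit_run(sim$web, sim$sol, sim$forcing, fit$best)
  last_t <- sim$forcing$temperature[length(sim$forcing$temperature)]
  proj_years <- (max(sim$forcing$years) + 1):(max(sim$forcing$years) + 40)
  warm <- climate_series(proj_years,
                         last_t + rcp_anomaly_series(proj_years, "rcp85")$value)
  fished <- sim$web$groups$name[sim$web$groups$catch > 0]
  f_last <- setNames(sim$forcing$f_mort[nrow(sim$forcing$f_mort), fished],
                     fished)
  scen <- list(
    status_quo = scenario_spec("status_quo", f_last, NULL,
                               min(proj_years), max(proj_years)),
    warming = scenario_spec("warming", f_last, warm,
                            min(proj_years), max(proj_years)))
  res <- lapply(scen, function(s)
    project_scenario(sim$web, sim$sol, arena_best, s,
                     state0 = hind$final_state, f_start = f_last))
  cumulative_report(res, path = file.path(out_dir, "cumulative_report.csv"))

  manifest <- list(seed = seed, n_trials = n_trials, max_v = max_v,
                   max_spline = max_spline, noise_cv = noise_cv,
                   package_version = as.character(utils::packageVersion("thermoweb")),
                   best_fit = fit$best$name)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, fit = fit, mc = env, rmsd = list(runs = runs,
                 holdouts = holds), scenarios = res))
}

# arena with the best-fit vulnerabilities substituted and recalibrated
best_fit_arena <- function(web, sol, fit_result) {
  v <- web$vulnerability
  v_by <- fit_result$v_by_predator
  if (!is.null(v_by) && length(v_by) > 0L) {
    idx <- group_index(web, names(v_by))
    v[, idx] <- rep(pmax(v_by, 1 + 1e-10), each = n_groups(web))
  }
  calibrate_arena(sol, v = v, d = web$handling)
}

# re-run a fitted configuration over a forcing window
refit_run <- function(web, sol, forcing, fit_result, ...) {
  fit_simulate(web, sol, forcing, v_by = fit_result$v_by_predator,
               anomaly = fit_result$anomaly, ...)
}
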