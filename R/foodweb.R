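#' Define a food-web model
#'
#' A `food_web` bundles the static description of an ecosystem: one row per
#' functional group (with the basic inputs biomass `B`, production/biomass
#' `P/B`, consumption/biomass `Q/B`, ecotrophic efficiency `EE`, and catch),
#' a diet-composition matrix, optional per-group thermal envelopes, and an
#' optional per-link vulnerability matrix. Fleets are collapsed to a single
#' aggregated catch (and hence fishing mortality) per group.
#'
#' Per group at most one of `biomass` and `ee` may be missing (`NA`); the
#' missing one is solved by [balance_model()]. Producers and detritus must
#' have `qb = 0`; detritus additionally has `pb = 0`.
#'
#' @param groups data.frame with columns `name`, `is_producer`,
#'   `is_detritus`, `biomass` (t km^-2), `pb` (yr^-1), `qb` (yr^-1), `ee`,
#'   `catch` (t km^-2 yr^-1) and optionally `stanza_partner` (name of a
#'   linked juvenile pool that matures into this one, or `NA`).
#' @param diet square numeric matrix, prey in rows, predators in columns,
#'   dimnames equal to the group names. Consumer columns must sum to 1;
#'   producer/detritus columns must be all zero.
#' @param thermal optional data.frame of thermal envelopes (see
#'   [read_thermal_csv()]) or a named list of [thermal_niche()] objects.
#' @param vulnerability optional numeric matrix of per-link vulnerabilities
#'   (>= 1); defaults to 2 everywhere (the neutral value).
#' @param config list of model options: `assimilation` (fraction of
#'   consumption assimilated, default 0.8), `stanza_rate` (first-order
#'   maturation rate yr^-1 for juvenile/adult pairs, default 0.5),
#'   `producer_cap` (producer carrying capacity as a multiple of baseline
#'   biomass, default 10), `tol` (balance tolerance, default 1e-8),
#'   `handling` (named per-predator handling times, default 1; `Inf`
#'   removes predator saturation for fast feeding links).
#' @return An object of class `food_web`.
#' @export
food_web <- function(groups, diet, thermal = NULL, vulnerability = NULL,
                     config = list()) {
  stopifnot(is.data.frame(groups))
  req <- c("name", "is_producer", "is_detritus", "biomass", "pb", "qb",
           "ee", "catch")
  miss <- setdiff(req, names(groups))
  if (length(miss) > 0L)
    stop("groups is missing columns: ", paste(miss, collapse = ", "))
  if (!"stanza_partner" %in% names(groups)) groups$stanza_partner <- NA_character_
  groups$name <- as.character(groups$name)
  groups$is_producer <- as.logical(groups$is_producer)
  groups$is_detritus <- as.logical(groups$is_detritus)
  if (anyDuplicated(groups$name))
    stop("duplicate group names")
  n <- nrow(groups)

  diet <- as.matrix(diet)
  if (!all(dim(diet) == c(n, n)))
    stop("diet matrix must be ", n, " x ", n)
  if (is.null(dimnames(diet))) dimnames(diet) <- list(groups$name, groups$name)
  diet <- diet[groups$name, groups$name, drop = FALSE]
  validate_diet(diet, groups)

  living <- !groups$is_detritus
  if (any(groups$pb[living] <= 0))
    stop("pb must be > 0 for living groups")
  if (any(groups$qb[groups$is_producer | groups$is_detritus] != 0))
    stop("producers and detritus must have qb = 0")
  if (any(groups$catch < 0, na.rm = TRUE))
    stop("catch must be >= 0")
  groups$catch[is.na(groups$catch)] <- 0
  n_unknown <- is.na(groups$biomass) + is.na(groups$ee)
  if (any(n_unknown[living] > 1))
    stop("at most one of {biomass, ee} may be missing per group: ",
         paste(groups$name[living][n_unknown[living] > 1], collapse = ", "))

  if (!is.null(vulnerability)) {
    vulnerability <- as.matrix(vulnerability)
    stopifnot(all(dim(vulnerability) == c(n, n)))
    if (any(vulnerability < 1))
      stop("vulnerabilities must be >= 1")
  } else {
    vulnerability <- matrix(2, n, n, dimnames = dimnames(diet))
  }

  if (is.data.frame(thermal)) thermal <- niches_from_table(thermal)
  if (!is.null(thermal)) {
    stopifnot(is.list(thermal))
    extra <- setdiff(names(thermal), groups$name)
    if (length(extra) > 0L)
      stop("thermal envelopes for unknown groups: ", paste(extra, collapse = ", "))
  }

  defaults <- list(assimilation = 0.8, stanza_rate = 0.5,
                   producer_cap = 10, tol = 1e-8)
  config <- utils::modifyList(defaults, config)

  # per-predator handling time (default 1; Inf = no predator saturation,
  # appropriate for fast plankton feeding links)
  handling <- rep(1, n)
  names(handling) <- groups$name
  if (!is.null(config$handling)) {
    h <- unlist(config$handling)
    handling[group_index_names(groups$name, names(h))] <- h
    config$handling <- NULL
  }

  structure(list(groups = groups, diet = diet, thermal = thermal,
                 vulnerability = vulnerability, handling = handling,
                 config = config),
            class = "food_web")
}

validate_diet <- function(diet, groups) {
  if (any(diet < 0)) stop("diet fractions must be >= 0")
  consumer <- !groups$is_producer & !groups$is_detritus
  csum <- colSums(diet)
  bad <- consumer & abs(csum - 1) > 1e-9
  if (any(bad))
    stop("consumer diet columns must sum to 1: ",
         paste(groups$name[bad], collapse = ", "))
  bad0 <- !consumer & csum != 0
  if (any(bad0))
    stop("producer/detritus diet columns must be zero: ",
         paste(groups$name[bad0], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.food_web <- function(x, ...) {
  g <- x$groups
  cat("food_web with", nrow(g), "groups (",
      sum(g$is_producer), "producer,", sum(g$is_detritus), "detritus )\n")
  cat("  consumers:",
      paste(g$name[!g$is_producer & !g$is_detritus], collapse = ", "), "\n")
  if (!is.null(x$thermal))
    cat("  thermal envelopes for", length(x$thermal), "groups\n")
  invisible(x)
}

n_groups <- function(web) nrow(web$groups)

group_index <- function(web, names) group_index_names(web$groups$name, names)

group_index_names <- function(all_names, names) {
  idx <- match(names, all_names)
  if (anyNA(idx))
    stop("unknown group(s): ", paste(names[is.na(idx)], collapse = ", "))
  idx
}
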