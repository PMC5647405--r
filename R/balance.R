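#' Solve the mass-balance baseline of a food web
#'
#' For every living group i the master balance
#' \deqn{B_i (P/B)_i EE_i = \sum_j B_j (Q/B)_j DC_{ij} + Y_i}
#' must hold, where the right-hand side is predation by all consumers j plus
#' the catch Y_i. Biomass accumulation and net migration are fixed at zero.
#' Per group exactly one of biomass and EE may be unknown: unknown biomasses
#' are solved jointly by linear elimination from the equations of those
#' groups (their EE must be supplied), after which EE follows directly for
#' every group with known biomass.
#'
#' The solution is flagged unbalanced (not an error) when any living EE
#' falls outside [0, 1]. Detritus groups are passive pools: their EE is the
#' ratio of detritus consumption plus catch to detrital inflow
#' (unassimilated consumption plus non-predation deaths), reported as a
#' diagnostic but never a balance constraint.
#'
#' @param web a [food_web()].
#' @return An object of class `ecopath_solution` with elements `biomass`,
#'   `ee`, `q0` (baseline consumption matrix, prey x predator,
#'   t km^-2 yr^-1), `m0` (other mortality, yr^-1), `g` (gross food
#'   conversion efficiency P/B / Q/B per consumer), `f0` (baseline fishing
#'   mortality catch/B, yr^-1), `balanced` flag and `det_inflow`.
#' @export
balance_model <- function(web) {
  g <- web$groups
  n <- nrow(g)
  living <- !g$is_detritus
  if (any(g$is_detritus & is.na(g$biomass)))
    stop("detritus biomass cannot be estimated; supply it for: ",
         paste(g$name[g$is_detritus & is.na(g$biomass)], collapse = ", "))

  B <- g$biomass
  EE <- g$ee
  Y <- g$catch
  QB <- g$qb
  PB <- g$pb
  DC <- web$diet

  unknownB <- which(is.na(B))
  if (length(unknownB) > 0L) {
    if (any(is.na(EE[unknownB])))
      stop("groups with unknown biomass need a known EE: ",
           paste(g$name[unknownB][is.na(EE[unknownB])], collapse = ", "))
    m <- length(unknownB)
    A <- matrix(0, m, m)
    rhs <- numeric(m)
    knownB <- setdiff(seq_len(n), unknownB)
    for (r in seq_len(m)) {
      i <- unknownB[r]
      A[r, r] <- PB[i] * EE[i] - QB[i] * DC[i, i]
      for (c in seq_len(m)) {
        j <- unknownB[c]
        if (j != i) A[r, c] <- A[r, c] - QB[j] * DC[i, j]
      }
      rhs[r] <- Y[i] + sum(B[knownB] * QB[knownB] * DC[i, knownB])
    }
    Bsol <- tryCatch(solve(A, rhs), error = function(e)
      stop("singular mass-balance system among groups with unknown biomass (",
           paste(g$name[unknownB], collapse = ", "),
           "): circular dependence cannot be eliminated", call. = FALSE))
    if (any(Bsol <= 0))
      stop("negative or zero biomass solved for: ",
           paste(g$name[unknownB][Bsol <= 0], collapse = ", "))
    B[unknownB] <- Bsol
  }

  # baseline consumption q0[i, j] = B_j * QB_j * DC_ij
  q0 <- DC * rep(B * QB, each = n)
  dimnames(q0) <- dimnames(DC)

  pred_loss <- rowSums(q0)
  solveEE <- setdiff(which(living), unknownB)
  EE[solveEE] <- (pred_loss[solveEE] + Y[solveEE]) / (B[solveEE] * PB[solveEE])

  m0 <- ifelse(living, PB * (1 - EE), 0)
  balanced <- all(EE[living] >= -1e-9 & EE[living] <= 1 + 1e-9)

  # detrital inflow: unassimilated consumption + non-predation deaths
  assim <- web$config$assimilation
  consumer <- living & QB > 0
  unassim <- (1 - assim) * sum(B[consumer] * QB[consumer])
  deaths <- sum(pmax(m0[living], 0) * B[living])
  det_idx <- which(g$is_detritus)
  det_inflow <- setNames(numeric(length(det_idx)), g$name[det_idx])
  if (length(det_idx) > 0L) {
    det_inflow[] <- (unassim + deaths) / length(det_idx)
    EE[det_idx] <- (pred_loss[det_idx] + Y[det_idx]) / det_inflow
  }

  gross <- ifelse(consumer, PB / ifelse(QB > 0, QB, 1), 0)
  f0 <- Y / B

  structure(list(
    biomass = setNames(B, g$name), ee = setNames(EE, g$name), q0 = q0,
    m0 = setNames(m0, g$name), g = setNames(gross, g$name),
    f0 = setNames(f0, g$name), balanced = balanced,
    det_inflow = det_inflow, living = setNames(living, g$name)),
    class = "ecopath_solution")
}

#' @export
print.ecopath_solution <- function(x, ...) {
  cat("ecopath_solution (", if (x$balanced) "balanced" else "UNBALANCED", ")\n")
  print(data.frame(biomass = round(x$biomass, 4), ee = round(x$ee, 4),
                   m0 = round(x$m0, 4), f0 = round(x$f0, 4)))
  invisible(x)
}

#' Decompose total mortality into predation, fishing and other
#'
#' Splits each living group's production rate P/B into the predation
#' mortality exerted by all consumers, the fishing mortality F = Y/B, and
#' the residual other mortality \eqn{(P/B)(1 - EE)}. The three components
#' sum to P/B by construction of the mass balance.
#'
#' @param sol an [balance_model()] solution.
#' @return data.frame with columns `group`, `predation`, `fishing`, `other`
#'   (all yr^-1), one row per living group.
#' @export
mortality_budget <- function(sol) {
  stopifnot(inherits(sol, "ecopath_solution"))
  if (any(sol$biomass <= 0)) stop("zero or negative biomass in solution")
  live <- which(sol$living)
  pred <- rowSums(sol$q0)[live] / sol$biomass[live]
  data.frame(group = names(sol$biomass)[live],
             predation = unname(pred),
             fishing = unname(sol$f0[live]),
             other = unname(sol$m0[live]),
             row.names = NULL)
}
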