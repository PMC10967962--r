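#' GIMME penalty coefficients
#'
#' Binarizes reaction expression evidence against the threshold: a
#' reaction expressed below the threshold is penalized proportionally to
#' the shortfall,
#' \deqn{c_i = \max(0, x_{threshold} - x_i),}
#' while reactions at or above the threshold -- and unscored reactions,
#' for which there is no evidence either way -- carry zero penalty.
#'
#' @param rxn_expr a \code{reaction_expression} from
#'   \code{\link{map_expression}}.
#' @param x_threshold the expression threshold (same scale as x_i).
#' @return a named non-negative numeric vector c_i over all reactions.
#' @export
compute_penalties <- function(rxn_expr, x_threshold) {
  if (!is.finite(x_threshold)) stop("x_threshold must be finite")
  x <- rxn_expr$x
  c_i <- ifelse(is.na(x), 0, pmax(0, x_threshold - x))
  stats::setNames(c_i, rxn_expr$reaction_id)
}

#' GIMME configuration
#'
#' @param growth_fraction fraction f in (0, 1] of the FBA maximum that the
#'   context-specific solution must still achieve. 1.0 pins growth at the
#'   unconstrained optimum; the default 0.90 follows the common GIMME
#'   practice of allowing a modest trade-off.
#' @param zero_tolerance absolute flux below which a reaction is called
#'   inactive.
#' @return a \code{gimme_config} list.
#' @export
gimme_config <- function(growth_fraction = 0.90, zero_tolerance = 1e-6) {
  if (growth_fraction <= 0 || growth_fraction > 1)
    stop("growth_fraction must be in (0, 1]")
  structure(list(growth_fraction = growth_fraction,
                 zero_tolerance = zero_tolerance),
            class = "gimme_config")
}

#' Solve the GIMME linear program
#'
#' Two-phase transcriptome integration. Phase 1 computes the FBA growth
#' maximum mu*. Phase 2 minimizes the total penalized absolute flux
#' \deqn{\sum_i c_i |v_i|}
#' subject to steady state S v = 0, the flux bounds, and a growth floor
#' v_biomass >= f mu*. The absolute value is handled exactly by splitting
#' each flux into nonnegative forward and reverse parts (valid because all
#' c_i >= 0). The optimum's objective is the inconsistency score: how much
#' below-threshold ("inactive" by expression) flux the network is still
#' forced to carry.
#'
#' @param model a \code{metabolic_model} with uptake bounds applied.
#' @param penalties named vector c_i from \code{\link{compute_penalties}}.
#' @param config a \code{\link{gimme_config}}.
#' @param objective_reaction_id growth reaction; defaults to biomass.
#' @return a \code{gimme_solution}: \code{status}, \code{fluxes} (named),
#'   \code{inconsistency_score}, \code{growth_rate}, \code{fba_maximum}.
#' @export
solve_gimme <- function(model, penalties, config = gimme_config(),
                        objective_reaction_id = model$biomass_id) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- model$reactions
  pen <- rep(0, nrow(rxns))
  names(pen) <- rxns$id
  pen[names(penalties)] <- penalties
  if (any(pen < 0)) stop("GIMME penalties must be non-negative")

  phase1 <- solve_fba(model, objective_reaction_id)
  if (phase1$status != "optimal")
    return(structure(list(status = phase1$status,
                          fluxes = phase1$fluxes,
                          inconsistency_score = NA_real_,
                          growth_rate = NA_real_,
                          fba_maximum = NA_real_),
                     class = "gimme_solution"))
  mu_star <- phase1$objective_value
  floor_value <- config$growth_fraction * mu_star

  n <- nrow(rxns)
  S <- as.matrix(model$stoichiometry)
  lb <- rxns$lb; ub <- rxns$ub
  # split v = p - m with p, m >= 0
  p_lb <- pmax(0, lb); p_ub <- pmax(0, ub)
  m_lb <- pmax(0, -ub); m_ub <- pmax(0, -lb)
  S2 <- cbind(S, -S)
  obj <- c(pen, pen)
  bio <- as.numeric(rxns$id == objective_reaction_id)
  ge <- list(A = matrix(c(bio, -bio), nrow = 1), b = floor_value)

  res <- solve_lp(obj, S2, rep(0, nrow(S)), c(p_lb, m_lb), c(p_ub, m_ub),
                  sense = "min", ge_rows = ge)
  if (res$status != "optimal")
    return(structure(list(status = res$status,
                          fluxes = stats::setNames(rep(NA_real_, n), rxns$id),
                          inconsistency_score = NA_real_,
                          growth_rate = NA_real_,
                          fba_maximum = mu_star),
                     class = "gimme_solution"))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  fluxes <- stats::setNames(v, rxns$id)
  if (max(abs(drop(S %*% v))) > 1e-6)
    stop("GIMME solution violates steady state beyond tolerance")
  growth <- unname(fluxes[objective_reaction_id])
  if (growth < floor_value - 1e-6)
    stop("GIMME solution violates the growth floor")
  structure(list(status = "optimal",
                 fluxes = fluxes,
                 inconsistency_score = sum(pen * abs(v)),
                 growth_rate = growth,
                 fba_maximum = mu_star),
            class = "gimme_solution")
}

#' @export
print.gimme_solution <- function(x, ...) {
  cat(sprintf("<gimme_solution> status: %s; growth %s of FBA max %s; inconsistency %s\n",
              x$status, format(x$growth_rate), format(x$fba_maximum),
              format(x$inconsistency_score)))
  invisible(x)
}

#' Classify reactions as active or inactive in a flux state
#'
#' A reaction is active when it carries flux beyond the zero tolerance
#' (which separates numerical LP noise from biological activity).
#'
#' @param solution a \code{gimme_solution} or \code{flux_solution} with
#'   status \code{"optimal"}.
#' @param zero_tolerance absolute flux cutoff; default 1e-6.
#' @return named character vector (\code{"active"}/\code{"inactive"}) over
#'   reactions.
#' @export
context_reaction_states <- function(solution, zero_tolerance = 1e-6) {
  if (!identical(solution$status, "optimal"))
    stop("reaction states require an optimal solution")
  stats::setNames(ifelse(abs(solution$fluxes) > zero_tolerance,
                         "active", "inactive"),
                  names(solution$fluxes))
}

#' Ids of active reactions in a solution
#'
#' @inheritParams context_reaction_states
#' @return character vector of reaction ids with \code{|v| >} tolerance.
#' @export
active_reactions <- function(solution, zero_tolerance = 1e-6) {
  st <- context_reaction_states(solution, zero_tolerance)
  names(st)[st == "active"]
}

#' Brute-force oracle for the GIMME phase-2 optimum
#'
#' Computes the exact minimum of the penalized absolute flux over the
#' growth-constrained polytope by enumerating its basic feasible points,
#' refined along the v_i = 0 hyperplanes of reversible reactions (where
#' the piecewise-linear objective kinks). Independent of the simplex
#' solver and of the flux-splitting reformulation. Limited to <= 12
#' reactions.
#'
#' @inheritParams solve_gimme
#' @return list with \code{status}, \code{fluxes},
#'   \code{inconsistency_score}, \code{growth_rate}.
#' @export
gimme_oracle <- function(model, penalties, config = gimme_config(),
                         objective_reaction_id = model$biomass_id) {
  rxns <- model$reactions
  if (nrow(rxns) > 12L)
    stop("GIMME oracle is limited to models with <= 12 reactions")
  pen <- rep(0, nrow(rxns)); names(pen) <- rxns$id
  pen[names(penalties)] <- penalties

  ofba <- enumerate_vertices_oracle(model, objective_reaction_id)
  if (ofba$status != "optimal")
    return(list(status = ofba$status, fluxes = ofba$fluxes,
                inconsistency_score = NA_real_, growth_rate = NA_real_))
  mu_star <- ofba$objective_value
  floor_value <- config$growth_fraction * mu_star

  # append the growth floor as an equality with a slack variable s >= 0:
  # v_bio - s = floor
  S <- as.matrix(model$stoichiometry)
  bio <- as.numeric(rxns$id == objective_reaction_id)
  A <- rbind(cbind(S, 0), c(bio, -1))
  b <- c(rep(0, nrow(S)), floor_value)
  lb <- c(rxns$lb, 0)
  ub <- c(rxns$ub, Inf)
  pts <- enumerate_basic_points(A, b, lb, ub, include_zero = TRUE)
  if (nrow(pts) == 0L)
    return(list(status = "infeasible",
                fluxes = stats::setNames(rep(NA_real_, nrow(rxns)), rxns$id),
                inconsistency_score = NA_real_, growth_rate = NA_real_))
  n <- nrow(rxns)
  scores <- drop(abs(pts[, seq_len(n), drop = FALSE]) %*% pen)
  best <- which.min(scores)
  v <- pts[best, seq_len(n)]
  list(status = "optimal",
       fluxes = stats::setNames(v, rxns$id),
       inconsistency_score = scores[best],
       growth_rate = unname(v[bio == 1]))
}
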