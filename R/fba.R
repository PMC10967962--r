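#' Build the stoichiometric matrix of a model
#'
#' Returns the sparse matrix S with entry (j, i) the signed coefficient of
#' metabolite j in reaction i (negative consumed, positive produced), row
#' order following the model's metabolite order and column order its
#' reaction order, together with the index maps.
#'
#' @param model a \code{metabolic_model}.
#' @return list with \code{S} (\code{dgCMatrix}), \code{metabolite_index},
#'   \code{reaction_index} (named integer vectors).
#' @export
build_stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- model$stoichiometry
  list(S = S,
       metabolite_index = stats::setNames(seq_len(nrow(S)), rownames(S)),
       reaction_index = stats::setNames(seq_len(ncol(S)), colnames(S)))
}

#' Constrain nutrient uptake through exchange reactions
#'
#' Applies the standard medium convention: uptake is negative exchange
#' flux. All exchange reactions are first closed to uptake (lb = 0,
#' secretion only), the listed open nutrients (e.g. ammonium, phosphate,
#' sulfate, water, protons) get lb = -1000 (unconstrained uptake), and
#' each measured carbon source gets lb = -rate with its upper bound
#' unchanged.
#'
#' @param model a \code{metabolic_model}.
#' @param constraints list of \code{uptake_constraint} objects (or of
#'   \code{list(exchange_reaction_id=, rate=)}) for measured carbon
#'   sources; rates are magnitudes in mmol/gDW/h.
#' @param open_nutrients character vector of exchange reaction ids left
#'   freely available.
#' @return the model with modified exchange bounds.
#' @export
apply_uptake <- function(model, constraints = list(),
                         open_nutrients = character(0)) {
  stopifnot(inherits(model, "metabolic_model"))
  ex <- exchange_ids(model)
  rxns <- model$reactions
  resolve <- function(id) {
    if (!id %in% ex)
      stop(sprintf("'%s' is not an exchange reaction of the model", id))
    id
  }
  rxns$lb[rxns$id %in% ex] <- 0
  for (id in open_nutrients)
    rxns$lb[rxns$id == resolve(id)] <- -1000
  for (ct in constraints) {
    id <- resolve(ct$exchange_reaction_id)
    if (is.null(ct$rate) || ct$rate < 0)
      stop(sprintf("uptake rate for '%s' must be a non-negative magnitude", id))
    rxns$lb[rxns$id == id] <- -ct$rate
  }
  model$reactions <- rxns
  model
}

#' Uptake constraint constructor
#'
#' @param exchange_reaction_id id of the exchange reaction.
#' @param rate non-negative uptake magnitude (mmol/gDW/h).
#' @return an \code{uptake_constraint} list.
#' @export
uptake_constraint <- function(exchange_reaction_id, rate) {
  if (rate < 0) stop("uptake rate must be non-negative")
  structure(list(exchange_reaction_id = exchange_reaction_id, rate = rate),
            class = "uptake_constraint")
}

flux_solution <- function(status, fluxes, objective_value) {
  structure(list(status = status, fluxes = fluxes,
                 objective_value = objective_value),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s; objective: %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes flux through the objective reaction (by default growth, i.e.
#' the biomass reaction) subject to steady state S v = 0 and the flux
#' bounds: the canonical FBA linear program.
#'
#' @param model a \code{metabolic_model}, typically after
#'   \code{\link{apply_uptake}}.
#' @param objective_reaction_id reaction whose flux is maximized; defaults
#'   to the biomass reaction.
#' @return a \code{flux_solution}: \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{fluxes} (named
#'   vector, mmol/gDW/h), \code{objective_value}.
#' @export
solve_fba <- function(model, objective_reaction_id = model$biomass_id) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- model$reactions
  if (!objective_reaction_id %in% rxns$id)
    stop(sprintf("objective reaction '%s' not in model", objective_reaction_id))
  n <- nrow(rxns)
  obj <- as.numeric(rxns$id == objective_reaction_id)
  res <- solve_lp(obj, as.matrix(model$stoichiometry), rep(0, nrow(model$stoichiometry)),
                  rxns$lb, rxns$ub, sense = "max")
  fluxes <- stats::setNames(res$x, rxns$id)
  if (res$status == "optimal") {
    resid <- max(abs(drop(as.matrix(model$stoichiometry) %*% res$x)), 0)
    if (resid > 1e-6) stop("FBA solution violates steady state beyond tolerance")
  }
  flux_solution(res$status, fluxes, res$objective)
}

#' Percent error between predicted and observed growth
#'
#' @param predicted,observed growth rates (1/h); \code{observed} must be
#'   positive.
#' @return \code{|predicted - observed| / observed * 100}.
#' @examples
#' growth_error_percent(0.9836, 1.0) # 1.64
#' @export
growth_error_percent <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed growth rate must be positive")
  abs(predicted - observed) / observed * 100
}

#' Brute-force LP oracle for tiny models
#'
#' Finds the exact FBA optimum by exhaustive enumeration of basic feasible
#' points of the flux polytope, entirely independent of the simplex
#' solver. Refuses models with more than 12 reactions.
#'
#' @inheritParams solve_fba
#' @return a \code{flux_solution}.
#' @export
enumerate_vertices_oracle <- function(model,
                                      objective_reaction_id = model$biomass_id) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- model$reactions
  if (nrow(rxns) > 12L)
    stop("vertex-enumeration oracle is limited to models with <= 12 reactions")
  if (!objective_reaction_id %in% rxns$id)
    stop(sprintf("objective reaction '%s' not in model", objective_reaction_id))
  A <- as.matrix(model$stoichiometry)
  pts <- enumerate_basic_points(A, rep(0, nrow(A)), rxns$lb, rxns$ub)
  obj <- as.numeric(rxns$id == objective_reaction_id)
  if (nrow(pts) == 0L)
    return(flux_solution("infeasible",
                         stats::setNames(rep(NA_real_, nrow(rxns)), rxns$id),
                         NA_real_))
  vals <- drop(pts %*% obj)
  best <- which.max(vals)
  x <- pts[best, ]
  ub <- ifelse(is.finite(rxns$ub), rxns$ub, LP_BIG)
  lb <- ifelse(is.finite(rxns$lb), rxns$lb, -LP_BIG)
  at_proxy <- obj != 0 & (x >= ub - 1e-6 & ub >= LP_BIG - 1 |
                          x <= lb + 1e-6 & lb <= -LP_BIG + 1)
  status <- if (abs(vals[best]) >= LP_UNBOUNDED_AT && any(at_proxy))
    "unbounded" else "optimal"
  flux_solution(status, stats::setNames(x, rxns$id), vals[best])
}
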