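#' Construct a genome-scale metabolic model
#'
#' The container mirrors the structure of a constraint-based metabolic
#' reconstruction: a metabolite table, a reaction table (bounds, GPR rule,
#' pathway label, kind), and the sparse stoichiometric matrix S with
#' metabolites as rows and reactions as columns. Negative coefficients are
#' consumed, positive produced. Exactly one reaction is the biomass
#' pseudo-reaction; its flux is the in silico growth rate (1/h). Flux units
#' are mmol/gDW/h throughout.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{lb}, \code{ub}, \code{gpr} (rule text or \code{NA}),
#'   \code{subsystem} (pathway label or \code{NA}), \code{kind} (one of
#'   \code{"enzymatic"}, \code{"spontaneous"}, \code{"transport"},
#'   \code{"exchange"}, \code{"biomass"}).
#' @param stoichiometry list mapping reaction id to a named numeric vector
#'   of metabolite coefficients, or a (metabolites x reactions) matrix.
#' @param compartments character vector of declared compartment codes;
#'   defaults to the codes used by \code{metabolites}.
#' @return an object of class \code{metabolic_model} with elements
#'   \code{metabolites}, \code{reactions}, \code{stoichiometry} (sparse
#'   \code{dgCMatrix}), \code{biomass_id}, \code{compartments},
#'   \code{genes} (union of GPR leaves).
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$gpr)) reactions$gpr <- NA_character_
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  if (is.null(compartments))
    compartments <- sort(unique(metabolites$compartment))

  nm <- nrow(metabolites)
  nr <- nrow(reactions)
  if (is.list(stoichiometry) && !is.data.frame(stoichiometry) &&
      !inherits(stoichiometry, "Matrix") && !is.matrix(stoichiometry)) {
    S <- Matrix::Matrix(0, nrow = nm, ncol = nr, sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      if (!rid %in% reactions$id)
        stop(sprintf("stoichiometry given for unknown reaction '%s'", rid))
      bad <- setdiff(names(coefs), metabolites$id)
      if (length(bad) > 0L)
        stop(sprintf("reaction '%s' references undeclared metabolite '%s'",
                     rid, bad[1]))
      S[names(coefs), rid] <- coefs
    }
  } else {
    S <- Matrix::Matrix(as.matrix(stoichiometry), sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }

  gprs <- lapply(reactions$gpr, function(g)
    if (is.na(g) || !nzchar(g)) NULL else parse_gpr(g))
  genes <- sort(unique(unlist(lapply(gprs, gpr_genes))))
  biomass_id <- reactions$id[reactions$kind == "biomass"]

  model <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = methods::as(S, "CsparseMatrix"),
    biomass_id = if (length(biomass_id) == 1L) biomass_id else NA_character_,
    compartments = compartments,
    genes = genes
  ), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique non-empty ids, declared
#' compartments, lb <= ub, exactly one biomass reaction, exchange reactions
#' touching exactly one metabolite, non-empty stoichiometry for
#' non-exchange reactions, and the gene set equalling the union of GPR
#' leaves.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  S <- model$stoichiometry
  if (anyDuplicated(mets$id)) {
    d <- mets$id[duplicated(mets$id)][1]
    stop(sprintf("duplicate metabolite id '%s'", d))
  }
  if (anyDuplicated(rxns$id)) {
    d <- rxns$id[duplicated(rxns$id)][1]
    stop(sprintf("duplicate reaction id '%s'", d))
  }
  if (nrow(mets) > 0 && (any(!nzchar(mets$id)) || anyNA(mets$id)))
    stop("empty metabolite id")
  if (nrow(rxns) > 0 && (any(!nzchar(rxns$id)) || anyNA(rxns$id)))
    stop("empty reaction id")
  bad_comp <- setdiff(mets$compartment, model$compartments)
  if (length(bad_comp) > 0L)
    stop(sprintf("metabolite compartment '%s' is not declared", bad_comp[1]))
  kinds <- c("enzymatic", "spontaneous", "transport", "exchange", "biomass")
  if (nrow(rxns) > 0 && !all(rxns$kind %in% kinds))
    stop(sprintf("unknown reaction kind '%s'",
                 setdiff(rxns$kind, kinds)[1]))
  if (any(rxns$lb > rxns$ub))
    stop(sprintf("reaction '%s' has lb > ub", rxns$id[rxns$lb > rxns$ub][1]))
  n_bio <- sum(rxns$kind == "biomass")
  if (nrow(rxns) > 0 && n_bio != 1L)
    stop(sprintf("model must have exactly one biomass reaction (found %d)",
                 n_bio))
  nz <- Matrix::colSums(S != 0)
  is_ex <- rxns$kind == "exchange"
  if (any(nz[is_ex] != 1L))
    stop(sprintf("exchange reaction '%s' must touch exactly one metabolite",
                 rxns$id[is_ex & nz != 1L][1]))
  if (any(nz[!is_ex] == 0L))
    stop(sprintf("reaction '%s' has empty stoichiometry",
                 rxns$id[!is_ex & nz == 0L][1]))
  gprs <- lapply(rxns$gpr, function(g)
    if (is.na(g) || !nzchar(g)) NULL else parse_gpr(g))
  leaves <- sort(unique(unlist(lapply(gprs, gpr_genes))))
  if (!identical(leaves, model$genes))
    stop("model gene set does not equal the union of GPR leaves")
  invisible(model)
}

#' Structural census of a model
#'
#' Counts genes, metabolites and reactions, split by reaction kind, the way
#' reconstruction papers tabulate model characteristics. Enzymatic
#' reactions are those with \code{kind == "enzymatic"}; everything else
#' (spontaneous, transport, exchange, biomass) counts as non-enzymatic.
#'
#' @param model a \code{metabolic_model}.
#' @return a list of class \code{model_census} with fields \code{n_genes},
#'   \code{n_metabolites}, \code{n_reactions}, \code{n_enzymatic},
#'   \code{n_nonenzymatic}, \code{n_spontaneous}, \code{n_transport},
#'   \code{n_exchange}, \code{n_biomass}.
#' @export
census <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  kind <- model$reactions$kind
  out <- list(
    n_genes = length(model$genes),
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    n_enzymatic = sum(kind == "enzymatic"),
    n_spontaneous = sum(kind == "spontaneous"),
    n_transport = sum(kind == "transport"),
    n_exchange = sum(kind == "exchange"),
    n_biomass = sum(kind == "biomass")
  )
  out$n_nonenzymatic <- out$n_reactions - out$n_enzymatic
  structure(out, class = "model_census")
}

#' @export
print.model_census <- function(x, ...) {
  cat("Model census\n")
  cat(sprintf("  genes        %6d\n", x$n_genes))
  cat(sprintf("  metabolites  %6d\n", x$n_metabolites))
  cat(sprintf("  reactions    %6d\n", x$n_reactions))
  cat(sprintf("    enzymatic     %6d\n", x$n_enzymatic))
  cat(sprintf("    non-enzymatic %6d\n", x$n_nonenzymatic))
  cat(sprintf("      spontaneous %6d\n", x$n_spontaneous))
  cat(sprintf("      transport   %6d\n", x$n_transport))
  cat(sprintf("      exchange    %6d\n", x$n_exchange))
  cat(sprintf("      biomass     %6d\n", x$n_biomass))
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions, %d genes\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  cat(sprintf("  biomass: %s; compartments: %s\n", x$biomass_id,
              paste(x$compartments, collapse = ", ")))
  invisible(x)
}

#' Exchange reaction ids of a model
#'
#' @param model a \code{metabolic_model}.
#' @return character vector.
#' @export
exchange_ids <- function(model) {
  model$reactions$id[model$reactions$kind == "exchange"]
}
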