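## SBML Level 3 Version 1 + FBC v2 reader/writer.
##
## Covers the constraint-based subset: compartments, species, flux bounds
## as global parameters referenced by fbc:lowerFluxBound/upperFluxBound,
## GPR rules as fbc:geneProductAssociation trees, the active objective as
## the biomass designation, and COBRA-style notes carrying the subsystem
## and reaction kind. Ids are written with the conventional M_/R_/G_
## prefixes and stripped on read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_escape_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' @rdname read_model
#' @usage NULL
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("not an SBML Level 3 document")

  strip <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = strip(xml2::xml_attr(sp_nodes, "id"), "M"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_labels <- stats::setNames(
    xml2::xml_attr(gp_nodes, "label"),
    xml2::xml_attr(gp_nodes, "id"))
  gp_labels[is.na(gp_labels)] <- sub("^G_", "", names(gp_labels)[is.na(gp_labels)])

  obj_ref <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  biomass_ref <- if (inherits(obj_ref, "xml_missing")) NA_character_ else
    strip(xml2::xml_attr(obj_ref, "reaction"), "R")

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rx_nodes)
  ids <- strip(xml2::xml_attr(rx_nodes, "id"), "R")
  stoich <- vector("list", n); names(stoich) <- ids
  lb <- ub <- numeric(n)
  gpr <- subsystem <- kind <- rep(NA_character_, n)
  nms <- xml2::xml_attr(rx_nodes, "name")

  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    refs <- function(xpath, sign) {
      sr <- xml2::xml_find_all(node, xpath, ns)
      if (length(sr) == 0L) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, strip(xml2::xml_attr(sr, "species"), "M"))
    }
    coefs <- c(refs("./s:listOfReactants/s:speciesReference", -1),
               refs("./s:listOfProducts/s:speciesReference", +1))
    agg <- tapply(coefs, names(coefs), sum)
    stoich[[i]] <- stats::setNames(as.numeric(agg), names(agg))

    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    rev_attr <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[i] <- if (!is.na(lbid) && lbid %in% names(par_vals)) par_vals[[lbid]]
             else if (rev_attr) -1000 else 0
    ub[i] <- if (!is.na(ubid) && ubid %in% names(par_vals)) par_vals[[ubid]]
             else 1000

    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(ga, "xml_missing"))
      gpr[i] <- format(sbml_parse_gpa(ga, ns, gp_labels))

    notes <- xml2::xml_text(xml2::xml_find_all(node, ".//s:notes//*[local-name()='p']", ns))
    for (p in notes) {
      if (grepl("^SUBSYSTEM:", p)) subsystem[i] <- trimws(sub("^SUBSYSTEM:", "", p))
      if (grepl("^KIND:", p)) kind[i] <- trimws(sub("^KIND:", "", p))
    }
  }

  if (anyNA(kind)) {
    n_touch <- vapply(stoich, length, integer(1))
    miss <- is.na(kind)
    kind[miss] <- ifelse(n_touch[miss] == 1L, "exchange",
                         ifelse(!is.na(gpr[miss]), "enzymatic", "spontaneous"))
    if (!is.na(biomass_ref)) kind[ids == biomass_ref] <- "biomass"
  }
  if (!any(kind == "biomass"))
    stop("SBML model designates no biomass reaction (no active objective)")

  reactions <- data.frame(id = ids, name = ifelse(is.na(nms), ids, nms),
                          lb = lb, ub = ub, gpr = gpr,
                          subsystem = subsystem, kind = kind,
                          stringsAsFactors = FALSE)
  bad <- setdiff(unique(unlist(lapply(stoich, names))), metabolites$id)
  if (length(bad) > 0L)
    stop(sprintf("SBML reaction references undeclared species '%s'", bad[1]))
  metabolic_model(metabolites, reactions, stoich, compartments = compartments)
}

sbml_parse_gpa <- function(node, ns, gp_labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    gene <- if (!is.na(ref) && ref %in% names(gp_labels)) gp_labels[[ref]]
            else sub("^G_", "", ref)
    return(structure(list(kind = "gene", gene = gene), class = "gpr_expr"))
  }
  children <- lapply(xml2::xml_children(node), sbml_parse_gpa, ns = ns,
                     gp_labels = gp_labels)
  gpr_node(if (nm == "and") "and" else "or", children)
}

#' @rdname write_model
#' @usage NULL
write_sbml <- function(model, path) {
  rx <- model$reactions
  S <- model$stoichiometry

  bounds <- unique(c(rx$lb, rx$ub))
  par_id <- function(v) paste0("FB_", gsub("[^0-9A-Za-z]", "_",
                               format(v, trim = TRUE, digits = 15)))
  par_ids <- stats::setNames(vapply(bounds, par_id, character(1)),
                             format(bounds, trim = TRUE, digits = 15))
  key <- function(v) format(v, trim = TRUE, digits = 15)

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in model$compartments)
    xml2::xml_add_child(loc, "compartment", id = cmp, constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(los, "species", id = paste0("M_", m$id),
                        name = m$name, compartment = m$compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in names(par_ids))
    xml2::xml_add_child(lop, "parameter", id = par_ids[[k]], value = k,
                        constant = "true")

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    rn <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", r$id),
                              name = r$name,
                              reversible = if (r$lb < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = par_ids[[key(r$lb)]],
                              "fbc:upperFluxBound" = par_ids[[key(r$ub)]])
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    if (!is.na(r$subsystem))
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    xml2::xml_add_child(body, "p", paste0("KIND: ", r$kind))

    col <- S[, i]
    neg <- col[col < 0]; pos <- col[col > 0]
    if (length(neg) > 0L) {
      lref <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(neg))
        xml2::xml_add_child(lref, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = key(-neg[[m]]), constant = "true")
    }
    if (length(pos) > 0L) {
      lref <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(pos))
        xml2::xml_add_child(lref, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = key(pos[[m]]), constant = "true")
    }
    if (!is.na(r$gpr) && nzchar(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_write_gpa(ga, parse_gpr(r$gpr))
    }
  }

  genes <- model$genes
  if (length(genes) > 0L) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_escape_id(g)),
                          "fbc:label" = g)
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$biomass_id),
                      "fbc:coefficient" = "1")

  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpa <- function(parent, expr) {
  if (expr$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_escape_id(expr$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", expr$kind))
    for (ch in expr$children) sbml_write_gpa(node, ch)
  }
}
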