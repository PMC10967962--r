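#' Read a metabolic model from disk
#'
#' Two on-disk dialects are supported: \code{"sbml_fbc"} (SBML Level 3
#' Version 1 with the FBC v2 package, the community standard for
#' constraint-based models) and \code{"tsv"}, a tabular dialect holding one
#' reactions table and one metabolites table (see Details).
#'
#' @details The TSV dialect is a directory (or file-pair prefix) with
#' \code{reactions.tsv} (columns \code{id}, \code{name}, \code{equation},
#' \code{lb}, \code{ub}, \code{gpr}, \code{subsystem}, \code{kind}; header
#' required, tab-separated, UTF-8) and \code{metabolites.tsv} (columns
#' \code{id}, \code{name}, \code{compartment}). Equations use
#' \code{"-->"} (irreversible) or \code{"<=>"} (reversible) arrows, e.g.
#' \code{"A_c + 2 B_c --> C_c"}; exchange reactions have one side empty.
#' Bounds left empty default to (-1000, 1000) for reversible and (0, 1000)
#' for irreversible reactions, the conventional finite proxy for
#' unbounded flux. If the \code{kind} column is absent it is inferred:
#' single-metabolite reactions are \code{exchange}; the reaction matching
#' \code{biomass_id} is \code{biomass}; otherwise \code{enzymatic} when a
#' GPR is present, else \code{spontaneous}.
#'
#' @param path file (SBML) or directory (TSV).
#' @param dialect \code{"sbml_fbc"} or \code{"tsv"}.
#' @param biomass_id optional reaction id used when the file does not
#'   designate a biomass reaction itself.
#' @return a validated \code{\link{metabolic_model}}.
#' @export
read_model <- function(path, dialect = c("sbml_fbc", "tsv"),
                       biomass_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("model path '%s' does not exist", path))
  switch(dialect,
         tsv = read_model_tsv(path, biomass_id = biomass_id),
         sbml_fbc = read_sbml(path))
}

#' Write a metabolic model to disk
#'
#' Inverse of \code{\link{read_model}}: reading the written file
#' reproduces the model up to field ordering (ids, stoichiometry, bounds
#' and GPR logic round-trip exactly).
#'
#' @param model a \code{metabolic_model}.
#' @param path output file (SBML) or directory (TSV; created if missing).
#' @param dialect \code{"sbml_fbc"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, dialect = c("sbml_fbc", "tsv")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  switch(dialect,
         tsv = write_model_tsv(model, path),
         sbml_fbc = write_sbml(model, path))
  invisible(path)
}

## ---- reaction equation strings -------------------------------------------

format_equation <- function(coefs, reversible) {
  arrow <- if (reversible) "<=>" else "-->"
  side <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, digits = 15), names(v))),
          collapse = " + ")
  }
  lhs <- side(coefs[coefs < 0])
  rhs <- side(coefs[coefs > 0])
  trimws(paste(lhs, arrow, rhs))
}

parse_equation <- function(eq, rid = "?") {
  rev <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev) "<=>" else "-->"
  if (!rev && !grepl("-->", eq, fixed = TRUE))
    stop(sprintf("reaction '%s': equation lacks an arrow ('-->' or '<=>')",
                 rid))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      if (!nzchar(term)) stop(sprintf("reaction '%s': empty term", rid))
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2L &&
                 !is.na(suppressWarnings(as.numeric(parts[1])))) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else {
        stop(sprintf("reaction '%s': cannot parse term '%s'", rid, term))
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  coefs <- lhs
  for (m in names(rhs)) coefs[m] <- (if (is.na(coefs[m])) 0 else coefs[m]) + rhs[m]
  list(coefs = coefs[coefs != 0], reversible = rev)
}

## ---- TSV dialect ----------------------------------------------------------

tsv_paths <- function(path) {
  if (dir.exists(path) || !grepl("\\.tsv$", path)) {
    list(rxn = file.path(path, "reactions.tsv"),
         met = file.path(path, "metabolites.tsv"),
         dir = path)
  } else {
    stop("TSV dialect expects a directory holding reactions.tsv and metabolites.tsv")
  }
}

read_model_tsv <- function(path, biomass_id = NULL) {
  p <- tsv_paths(path)
  for (f in c(p$rxn, p$met))
    if (!file.exists(f)) stop(sprintf("missing TSV table '%s'", f))
  rx <- utils::read.delim(p$rxn, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  mt <- utils::read.delim(p$met, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need_rx <- c("id", "equation")
  if (!all(need_rx %in% names(rx)))
    stop("reactions.tsv must have at least columns: id, equation")
  if (!all(c("id", "compartment") %in% names(mt)))
    stop("metabolites.tsv must have at least columns: id, compartment")
  if (anyDuplicated(rx$id))
    stop(sprintf("duplicate reaction id '%s' in reactions.tsv",
                 rx$id[duplicated(rx$id)][1]))
  if (anyDuplicated(mt$id))
    stop(sprintf("duplicate metabolite id '%s' in metabolites.tsv",
                 mt$id[duplicated(mt$id)][1]))

  parsed <- lapply(seq_len(nrow(rx)), function(i)
    parse_equation(rx$equation[i], rx$id[i]))
  stoich <- lapply(parsed, `[[`, "coefs")
  names(stoich) <- rx$id
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")

  num_or_na <- function(col) {
    if (is.null(col)) return(rep(NA_real_, nrow(rx)))
    suppressWarnings(as.numeric(ifelse(nzchar(trimws(col)), col, NA)))
  }
  lb <- num_or_na(rx$lb); ub <- num_or_na(rx$ub)
  lb[is.na(lb)] <- ifelse(reversible[is.na(lb)], -1000, 0)
  ub[is.na(ub)] <- 1000

  gpr <- if (is.null(rx$gpr)) rep(NA_character_, nrow(rx)) else
    ifelse(nzchar(trimws(rx$gpr)), rx$gpr, NA_character_)
  subsystem <- if (is.null(rx$subsystem)) rep(NA_character_, nrow(rx)) else
    ifelse(nzchar(trimws(rx$subsystem)), rx$subsystem, NA_character_)

  if (is.null(rx$kind) || !any(nzchar(trimws(rx$kind)))) {
    n_touch <- vapply(stoich, length, integer(1))
    kind <- ifelse(n_touch == 1L, "exchange",
                   ifelse(!is.na(gpr), "enzymatic", "spontaneous"))
    if (!is.null(biomass_id)) kind[rx$id == biomass_id] <- "biomass"
    if (!any(kind == "biomass"))
      stop("no biomass reaction: TSV lacks a kind column and no biomass_id was given")
  } else {
    kind <- trimws(rx$kind)
  }

  reactions <- data.frame(
    id = rx$id,
    name = if (is.null(rx$name)) rx$id else rx$name,
    lb = lb, ub = ub, gpr = gpr, subsystem = subsystem, kind = kind,
    stringsAsFactors = FALSE)
  metabolites <- data.frame(
    id = mt$id,
    name = if (is.null(mt$name)) mt$id else mt$name,
    compartment = mt$compartment, stringsAsFactors = FALSE)

  bad <- setdiff(unique(unlist(lapply(stoich, names))), metabolites$id)
  if (length(bad) > 0L) {
    off <- rx$id[vapply(stoich, function(s) bad[1] %in% names(s), logical(1))][1]
    stop(sprintf("reaction '%s' references undeclared metabolite '%s'",
                 off, bad[1]))
  }
  metabolic_model(metabolites, reactions, stoich)
}

write_model_tsv <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  S <- model$stoichiometry
  rx <- model$reactions
  eqs <- vapply(seq_len(nrow(rx)), function(i) {
    col <- S[, i]
    format_equation(col[col != 0], rx$lb[i] < 0)
  }, character(1))
  out_rx <- data.frame(
    id = rx$id, name = rx$name, equation = eqs,
    lb = format(rx$lb, trim = TRUE, digits = 15),
    ub = format(rx$ub, trim = TRUE, digits = 15),
    gpr = ifelse(is.na(rx$gpr), "", rx$gpr),
    subsystem = ifelse(is.na(rx$subsystem), "", rx$subsystem),
    kind = rx$kind, stringsAsFactors = FALSE)
  utils::write.table(out_rx, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites, file.path(path, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
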