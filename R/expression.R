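#' Read an FPKM expression table
#'
#' Expects a tab-separated file with a \code{gene_id} column followed by
#' one numeric column per condition (e.g. light-glucose \code{LG} and
#' light-sucrose \code{LS}).
#'
#' @param path TSV file path.
#' @return a named list of \code{expression_profile} objects, one per
#'   condition column; each has \code{condition} and \code{values} (named
#'   non-negative numeric vector of FPKM).
#' @export
read_fpkm <- function(path) {
  if (!file.exists(path)) stop(sprintf("FPKM file '%s' does not exist", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("FPKM table must have a gene_id column and at least one condition column")
  gene_col <- names(tab)[1]
  genes <- as.character(tab[[gene_col]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene row '%s' in FPKM table",
                 genes[duplicated(genes)][1]))
  conds <- names(tab)[-1]
  out <- lapply(conds, function(cn) {
    raw <- tab[[cn]]
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v))
      stop(sprintf("non-numeric FPKM value '%s' in condition '%s'",
                   raw[which(is.na(v))[1]], cn))
    if (any(v < 0))
      stop(sprintf("negative FPKM value in condition '%s'", cn))
    expression_profile(cn, stats::setNames(v, genes))
  })
  stats::setNames(out, conds)
}

#' Expression profile constructor
#'
#' @param condition condition label (e.g. \code{"LS"}).
#' @param values named non-negative numeric vector of FPKM per gene.
#' @return an \code{expression_profile}.
#' @export
expression_profile <- function(condition, values) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("expression values must be uniquely named by gene id")
  if (any(values < 0)) stop("FPKM values must be non-negative")
  structure(list(condition = condition, values = values),
            class = "expression_profile")
}

#' Expression threshold from a percentile
#'
#' Computes the expression level below which a reaction is considered
#' penalizable: the given percentile (linear interpolation between order
#' statistics) of either the metabolic genes of the model present in the
#' profile (default -- the gene population a metabolic reconstruction
#' carries) or of all genes in the profile.
#'
#' @param profile an \code{expression_profile}.
#' @param model a \code{metabolic_model}; required for
#'   \code{population = "metabolic_genes"}.
#' @param percentile value in \code{[0, 100]}; default 50 (the median).
#' @param population \code{"metabolic_genes"} or \code{"all_genes"}.
#' @return the threshold (FPKM scale).
#' @examples
#' p <- expression_profile("x", c(g1 = 1, g2 = 2, g3 = 3, g4 = 4))
#' compute_threshold(p, model = NULL, percentile = 50,
#'                   population = "all_genes") # 2.5
#' @export
compute_threshold <- function(profile, model = NULL, percentile = 50,
                              population = c("metabolic_genes", "all_genes")) {
  population <- match.arg(population)
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  vals <- profile$values
  if (population == "metabolic_genes") {
    if (is.null(model)) stop("a model is required to restrict to metabolic genes")
    vals <- vals[names(vals) %in% model$genes]
  }
  if (length(vals) == 0L)
    stop("empty gene population for threshold computation")
  unname(stats::quantile(vals, probs = percentile / 100, type = 7))
}

#' Map gene expression onto reactions
#'
#' Assigns every reaction with a GPR rule an expression score x_i.
#' \code{"max_over_genes"} (default) takes the maximum over the rule's
#' genes, reflecting the assumption that a reaction is active as soon as
#' at least one associated gene is expressed; \code{"gpr_aware"}
#' aggregates through the rule (complexes \code{and} -> min, isozymes
#' \code{or} -> max). Reactions without a GPR, or whose genes are all
#' absent from the profile, stay unscored: missing evidence is not treated
#' as silence.
#'
#' @param model a \code{metabolic_model}.
#' @param profile an \code{expression_profile}.
#' @param rule \code{"max_over_genes"} or \code{"gpr_aware"}.
#' @return a \code{reaction_expression}: data.frame with columns
#'   \code{reaction_id}, \code{x} (NA when unscored), \code{scored}.
#' @export
map_expression <- function(model, profile,
                           rule = c("max_over_genes", "gpr_aware")) {
  rule <- match.arg(rule)
  vals <- profile$values
  rxns <- model$reactions
  x <- rep(NA_real_, nrow(rxns))
  for (i in seq_len(nrow(rxns))) {
    g <- rxns$gpr[i]
    if (is.na(g) || !nzchar(g)) next
    tree <- parse_gpr(g)
    if (rule == "max_over_genes") {
      present <- intersect(gpr_genes(tree), names(vals))
      if (length(present) > 0L) x[i] <- max(vals[present])
    } else {
      x[i] <- gpr_eval(tree, vals)
    }
  }
  structure(data.frame(reaction_id = rxns$id, x = x, scored = !is.na(x),
                       stringsAsFactors = FALSE),
            class = c("reaction_expression", "data.frame"),
            mapping_rule = rule, condition = profile$condition)
}

#' Bin FPKM values into the conventional expression-level categories
#'
#' Counts genes per FPKM bin: below 1, [1, 10), [10, 100) and >= 100, the
#' categories expression atlases report. Genes below the expressed floor
#' (default: FPKM of exactly 0) are reported separately as the
#' not-expressed count.
#'
#' @param profile an \code{expression_profile}.
#' @param expressed_floor a gene counts as expressed when its FPKM exceeds
#'   this floor (strict); default 0.
#' @return list with \code{counts} (named vector over the four bins),
#'   \code{not_expressed}, \code{n_genes},
#'   \code{expressed_fraction} (percent).
#' @export
bin_expression <- function(profile, expressed_floor = 0) {
  v <- profile$values
  expressed <- v > expressed_floor
  e <- v[expressed]
  counts <- c(
    "sub1" = sum(e < 1),
    "1-10" = sum(e >= 1 & e < 10),
    "10-100" = sum(e >= 10 & e < 100),
    ">=100" = sum(e >= 100)
  )
  list(counts = counts,
       not_expressed = sum(!expressed),
       n_genes = length(v),
       expressed_fraction = 100 * sum(expressed) / length(v))
}
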