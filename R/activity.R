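#' Venn partition of two active-reaction sets
#'
#' Splits the active reactions of two culture conditions into
#' condition-specific and core (shared) sets, the comparison underlying a
#' two-set Venn diagram.
#'
#' @param active_a,active_b character vectors of reaction ids.
#' @return a \code{venn_partition} list: \code{only_a}, \code{only_b},
#'   \code{core} (sorted, pairwise disjoint), \code{union_size}.
#' @examples
#' compare_conditions(c("r1", "r2"), c("r2", "r3"))
#' @export
compare_conditions <- function(active_a, active_b) {
  a <- unique(active_a); b <- unique(active_b)
  out <- list(only_a = sort(setdiff(a, b)),
              only_b = sort(setdiff(b, a)),
              core = sort(intersect(a, b)))
  out$union_size <- length(out$only_a) + length(out$only_b) + length(out$core)
  structure(out, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> only A: %d; only B: %d; core: %d; union: %d\n",
              length(x$only_a), length(x$only_b), length(x$core),
              x$union_size))
  invisible(x)
}

#' Classify a reaction set by pathway annotation
#'
#' Tallies the reactions of a set by their subsystem label (KEGG-style
#' pathway category) as annotated in the model; no external database is
#' consulted. A reaction carrying several semicolon-separated labels
#' counts once under its first label unless \code{multi_count} is set.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_set character vector of reaction ids.
#' @param multi_count logical; count a multi-label reaction under every
#'   label.
#' @return a \code{pathway_breakdown} list: \code{counts} (named integer
#'   vector, decreasing) and \code{unclassified}.
#' @export
classify_by_pathway <- function(model, reaction_set, multi_count = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  reaction_set <- unique(reaction_set)
  missing <- setdiff(reaction_set, model$reactions$id)
  if (length(missing) > 0L)
    stop(sprintf("reaction '%s' not in model", missing[1]))
  sub <- model$reactions$subsystem[match(reaction_set, model$reactions$id)]
  labelled <- !is.na(sub) & nzchar(sub)
  labels <- strsplit(sub[labelled], ";", fixed = TRUE)
  labels <- lapply(labels, trimws)
  if (!multi_count) labels <- lapply(labels, `[`, 1)
  tab <- table(unlist(labels))
  counts <- sort(stats::setNames(as.integer(tab), names(tab)),
                 decreasing = TRUE)
  structure(list(counts = counts, unclassified = sum(!labelled)),
            class = "pathway_breakdown")
}

#' @export
print.pathway_breakdown <- function(x, ...) {
  cat("<pathway_breakdown>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-45s %5d\n", nm, x$counts[[nm]]))
  cat(sprintf("  %-45s %5d\n", "(unclassified)", x$unclassified))
  invisible(x)
}
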