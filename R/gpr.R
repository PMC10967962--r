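#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules link genes to the reactions their products catalyse: \code{and}
#' denotes an enzyme complex (all subunits required), \code{or} denotes
#' isozymes (any one suffices). The grammar accepts gene identifiers,
#' case-insensitive keywords \code{and}/\code{or}, and parentheses;
#' \code{and} binds tighter than \code{or}.
#'
#' @param text a single character string, e.g. \code{"(g1 and g2) or g3"}.
#' @return an object of class \code{gpr_expr}: a recursive list with
#'   \code{kind} one of \code{"gene"}, \code{"and"}, \code{"or"}; gene nodes
#'   carry \code{gene}, boolean nodes carry \code{children} (always >= 2).
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' format(g)
#' gpr_genes(g)
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("GPR text must be a single character string")
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0L) stop("empty GPR expression")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks))
    stop(sprintf("unexpected token '%s' at position %d in GPR",
                 st$toks$text[st$pos], st$toks$at[st$pos]))
  expr
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1L) return(data.frame(text = character(), at = integer()))
  pieces <- regmatches(text, gregexpr(pat, text))[[1]]
  data.frame(text = pieces, at = as.integer(m), stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks$text[st$pos]
}

gpr_take <- function(st) {
  tok <- gpr_peek(st)
  st$pos <- st$pos + 1L
  tok
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (!is.null(tok <- gpr_peek(st)) && tolower(tok) == "or") {
    gpr_take(st)
    children <- c(children, list(gpr_parse_and(st)))
  }
  if (length(children) == 1L) children[[1]] else gpr_node("or", children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (!is.null(tok <- gpr_peek(st)) && tolower(tok) == "and") {
    gpr_take(st)
    children <- c(children, list(gpr_parse_atom(st)))
  }
  if (length(children) == 1L) children[[1]] else gpr_node("and", children)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  at <- if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else nchar(st$toks$text[1])
  if (is.null(tok))
    stop("dangling operator at end of GPR expression")
  if (tok == "(") {
    gpr_take(st)
    inner <- gpr_parse_or(st)
    closing <- gpr_take(st)
    if (is.null(closing) || closing != ")")
      stop(sprintf("unbalanced parenthesis opened at position %d", at))
    return(inner)
  }
  if (tok == ")")
    stop(sprintf("unbalanced closing parenthesis at position %d", at))
  if (tolower(tok) %in% c("and", "or"))
    stop(sprintf("dangling operator '%s' at position %d", tok, at))
  gpr_take(st)
  structure(list(kind = "gene", gene = tok), class = "gpr_expr")
}

gpr_node <- function(kind, children) {
  # flatten nested same-operator nodes so and/or always have >= 2 children
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr_expr")
}

#' Serialize a GPR tree back to text
#'
#' The output re-parses to a logically identical tree: \code{or} children of
#' an \code{and} node are parenthesized, everything else relies on
#' precedence.
#'
#' @param x a \code{gpr_expr}.
#' @param ... unused.
#' @return a character string.
#' @export
format.gpr_expr <- function(x, ...) {
  switch(x$kind,
    gene = x$gene,
    and = paste(vapply(x$children, function(ch) {
      s <- format(ch)
      if (ch$kind == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    or = paste(vapply(x$children, format, character(1)), collapse = " or ")
  )
}

#' @export
print.gpr_expr <- function(x, ...) {
  cat("<gpr> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR tree
#'
#' @param x a \code{gpr_expr} (or \code{NULL}, giving \code{character(0)}).
#' @return sorted unique character vector of gene ids.
#' @export
gpr_genes <- function(x) {
  if (is.null(x)) return(character(0))
  if (x$kind == "gene") return(x$gene)
  sort(unique(unlist(lapply(x$children, gpr_genes))))
}

#' Evaluate a GPR tree over per-gene scores
#'
#' Used by GPR-aware expression mapping: \code{and} aggregates with
#' \code{min} (a complex is limited by its scarcest subunit), \code{or}
#' with \code{max} (isozymes are interchangeable). Genes absent from
#' \code{scores} are dropped from their aggregation; a node with no scored
#' gene evaluates to \code{NA}.
#'
#' @param x a \code{gpr_expr}.
#' @param scores named numeric vector of per-gene values.
#' @return a numeric scalar or \code{NA_real_}.
#' @export
gpr_eval <- function(x, scores) {
  if (is.null(x)) return(NA_real_)
  if (x$kind == "gene") {
    v <- scores[x$gene]
    return(if (length(v) == 1L && !is.na(v)) unname(v) else NA_real_)
  }
  vals <- vapply(x$children, gpr_eval, numeric(1), scores = scores)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (x$kind == "and") min(vals) else max(vals)
}
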