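# shared fixtures built in code

textbook_with_uptake <- function(rate = 10) {
  m <- make_textbook_model()
  apply_uptake(m, list(uptake_constraint("EX_A", rate)),
               open_nutrients = "EX_N")
}

# textbook model with the parallel paths blocked, leaving R_hi the only
# route A -> B
textbook_forced_path <- function(rate = 10) {
  m <- textbook_with_uptake(rate)
  m$reactions$ub[m$reactions$id %in% c("R_lo", "R_byp")] <- 0
  m
}

random_gpr_tree <- function(depth = 3, genes = sprintf("g%d", 1:8)) {
  if (depth == 0 || stats::runif(1) < 0.4) {
    return(structure(list(kind = "gene", gene = sample(genes, 1)),
                     class = "gpr_expr"))
  }
  kind <- sample(c("and", "or"), 1)
  n_ch <- sample(2:3, 1)
  children <- replicate(n_ch, random_gpr_tree(depth - 1, genes),
                        simplify = FALSE)
  # flatten like the parser does so round-trips compare equal
  tigsmm:::gpr_node(kind, children)
}

gpr_logically_equal <- function(a, b, genes) {
  # truth-table comparison over all assignments of the mentioned genes
  eval_bool <- function(x, on) {
    if (x$kind == "gene") return(x$gene %in% on)
    vals <- vapply(x$children, eval_bool, logical(1), on = on)
    if (x$kind == "and") all(vals) else any(vals)
  }
  for (i in 0:(2^length(genes) - 1)) {
    on <- genes[bitwAnd(i, 2^(seq_along(genes) - 1)) > 0]
    if (eval_bool(a, on) != eval_bool(b, on)) return(FALSE)
  }
  TRUE
}
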