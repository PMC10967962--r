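## Synthetic-data generators.
##
## These produce every input the pipeline consumes -- a feasible toy
## metabolic network, FPKM tables with plantable low-expression reactions,
## and gene-level differential statistics with planted "hot" metabolite
## neighborhoods -- so that each stage can be exercised and property-tested
## at desk scale. Synthetic gene ids use the CCMX_ prefix so they can never
## collide with real CCM_ locus tags.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Hand-written textbook fixture model
#'
#' A 6-metabolite, 10-reaction, 4-gene network with every structural
#' feature the pipeline cares about: a carbon exchange (\code{EX_A}), a
#' nutrient exchange (\code{EX_N}), a secretion exchange (\code{EX_D}),
#' two transporters, two parallel unit-yield paths A -> B carrying
#' different genes (\code{R_hi}, \code{R_lo}), a half-yield bypass
#' (\code{R_byp}: A -> 0.5 B + 0.5 D) carrying its own gene, one
#' spontaneous reaction, and a biomass reaction draining B + C.
#' With carbon uptake u, maximal growth is u (via either parallel path)
#' and the bypass alone sustains growth u/2.
#'
#' @return a validated \code{metabolic_model}.
#' @export
make_textbook_model <- function() {
  metabolites <- data.frame(
    id = c("A_e", "N_e", "A_c", "B_c", "C_c", "D_c"),
    name = c("carbon (extracellular)", "nutrient (extracellular)",
             "carbon (cytosol)", "precursor B", "precursor C", "byproduct D"),
    compartment = c("e", "e", "c", "c", "c", "c"),
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("EX_A", "EX_N", "EX_D", "T_A", "T_N",
           "R_hi", "R_lo", "R_byp", "R_spont", "BIOMASS"),
    name = c("carbon exchange", "nutrient exchange", "byproduct exchange",
             "carbon transport", "nutrient transport",
             "high-expression path", "low-expression path",
             "half-yield bypass", "spontaneous drain", "biomass"),
    lb = c(-1000, -1000, 0, 0, 0, 0, 0, 0, 0, 0),
    ub = rep(1000, 10),
    gpr = c(NA, NA, NA, "CCMX_0004", "CCMX_0004",
            "CCMX_0001", "CCMX_0002", "CCMX_0003", NA, NA),
    subsystem = c(NA, NA, NA, "membrane transport", "membrane transport",
                  "glycolysis", "glycolysis", "pentose phosphate pathway",
                  NA, NA),
    kind = c("exchange", "exchange", "exchange", "transport", "transport",
             "enzymatic", "enzymatic", "enzymatic", "spontaneous",
             "biomass"),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A = c(A_e = -1),
    EX_N = c(N_e = -1),
    EX_D = c(D_c = -1),
    T_A = c(A_e = -1, A_c = 1),
    T_N = c(N_e = -1, C_c = 1),
    R_hi = c(A_c = -1, B_c = 1),
    R_lo = c(A_c = -1, B_c = 1),
    R_byp = c(A_c = -1, B_c = 0.5, D_c = 0.5),
    R_spont = c(C_c = -1, D_c = 1),
    BIOMASS = c(B_c = -1, C_c = -1)
  )
  metabolic_model(metabolites, reactions, stoich)
}

#' Generate a random feasible toy metabolic model
#'
#' Builds a linear backbone (substrate exchange, transport, a chain of
#' unit-yield conversions, biomass) that guarantees positive growth by
#' construction, then adds parallel duplicate reactions (isozyme-like,
#' different genes) and forward branch reactions until \code{n_reactions}
#' is reached. Every added reaction gets a random GPR over a synthetic
#' gene universe. Fully deterministic per seed.
#'
#' @param n_metabolites total metabolites (>= 3: one extracellular
#'   substrate plus an internal chain).
#' @param n_reactions total reactions (>= backbone size, which is
#'   \code{n_metabolites + 1}).
#' @param n_genes size of the synthetic gene universe; default 2 *
#'   n_reactions.
#' @param reversible_fraction fraction of added internal reactions made
#'   reversible.
#' @param seed integer seed.
#' @return a validated \code{metabolic_model} whose carbon exchange is
#'   \code{EX_S}.
#' @export
generate_model <- function(n_metabolites = 5, n_reactions = 8,
                           n_genes = 2 * n_reactions,
                           reversible_fraction = 0.25, seed = 1) {
  if (n_metabolites < 3) stop("need at least 3 metabolites")
  backbone <- n_metabolites + 1L  # EX_S, T_S, chain (n_mets - 2), biomass
  if (n_reactions < backbone)
    stop(sprintf("need at least %d reactions for %d metabolites",
                 backbone, n_metabolites))
  with_seed(seed, {
    n_int <- n_metabolites - 1L
    mets <- data.frame(
      id = c("S_e", paste0("M", seq_len(n_int), "_c")),
      name = c("substrate", paste0("intermediate ", seq_len(n_int))),
      compartment = c("e", rep("c", n_int)),
      stringsAsFactors = FALSE)
    genes <- sprintf("CCMX_%04d", seq_len(n_genes))
    rand_gpr <- function() {
      k <- sample(1:3, 1)
      g <- sample(genes, k)
      if (k == 1) g else paste(g, collapse = sample(c(" and ", " or "), 1))
    }
    ids <- c("EX_S", "T_S")
    stoich <- list(EX_S = c(S_e = -1),
                   T_S = c(S_e = -1, M1_c = 1))
    gpr <- c(NA, rand_gpr())
    kind <- c("exchange", "transport")
    rev <- c(TRUE, FALSE)
    if (n_int >= 2) {
      for (i in seq_len(n_int - 1L)) {
        rid <- sprintf("R%03d", i)
        ids <- c(ids, rid)
        stoich[[rid]] <- stats::setNames(c(-1, 1),
                                         paste0(c(sprintf("M%d_c", i),
                                                  sprintf("M%d_c", i + 1))))
        gpr <- c(gpr, rand_gpr())
        kind <- c(kind, "enzymatic")
        rev <- c(rev, FALSE)
      }
    }
    ids <- c(ids, "BIOMASS")
    stoich$BIOMASS <- stats::setNames(-1, sprintf("M%d_c", n_int))
    gpr <- c(gpr, NA)
    kind <- c(kind, "biomass")
    rev <- c(rev, FALSE)

    extra <- n_reactions - length(ids)
    for (j in seq_len(extra)) {
      rid <- sprintf("X%03d", j)
      if (n_int >= 2 && stats::runif(1) < 0.6) {
        # parallel duplicate of a chain step (an isozyme path)
        i <- sample(seq_len(n_int - 1L), 1)
        stoich[[rid]] <- stats::setNames(c(-1, 1),
                                         c(sprintf("M%d_c", i),
                                           sprintf("M%d_c", i + 1)))
      } else {
        # forward branch skipping ahead (or a drain back to the chain end)
        from <- sample(seq_len(n_int), 1)
        to <- if (from < n_int) sample(seq(from + 1L, n_int), 1) else from - 1L
        stoich[[rid]] <- stats::setNames(c(-1, stats::runif(1, 0.5, 1)),
                                         c(sprintf("M%d_c", from),
                                           sprintf("M%d_c", to)))
      }
      ids <- c(ids, rid)
      gpr <- c(gpr, rand_gpr())
      kind <- c(kind, "enzymatic")
      rev <- c(rev, stats::runif(1) < reversible_fraction)
    }
    reactions <- data.frame(
      id = ids, name = ids,
      lb = ifelse(rev, -1000, 0), ub = 1000,
      gpr = gpr,
      subsystem = sample(c("glycolysis", "tca cycle", "lipid metabolism",
                           NA_character_), length(ids), replace = TRUE),
      kind = kind, stringsAsFactors = FALSE)
    reactions$subsystem[kind %in% c("exchange", "biomass")] <- NA
    m <- metabolic_model(mets, reactions, stoich)
    m
  })
}

#' Generate synthetic FPKM profiles for a model's genes
#'
#' Draws log-normal FPKM values (the shape bulk RNA-seq expression
#' roughly follows) independently for each condition. Genes of
#' \code{planted_low_reactions} are instead drawn from the bottom tail of
#' the same distribution (below its 5th percentile), so the planted
#' reactions fall below any median-style threshold.
#'
#' @param model a \code{metabolic_model}.
#' @param conditions character vector of condition labels.
#' @param meanlog,sdlog log-scale parameters of the FPKM distribution.
#' @param planted_low_reactions reaction ids whose genes are forced low.
#' @param seed integer seed.
#' @return named list of \code{expression_profile}, one per condition.
#' @export
generate_fpkm <- function(model, conditions = c("LG", "LS"),
                          meanlog = 2, sdlog = 1.2,
                          planted_low_reactions = character(0), seed = 1) {
  stopifnot(inherits(model, "metabolic_model"))
  genes <- model$genes
  rxns <- model$reactions
  low_genes <- unique(unlist(lapply(planted_low_reactions, function(rid) {
    g <- rxns$gpr[rxns$id == rid]
    if (length(g) == 0L) stop(sprintf("planted reaction '%s' not in model", rid))
    if (is.na(g)) character(0) else gpr_genes(parse_gpr(g))
  })))
  with_seed(seed, {
    out <- lapply(conditions, function(cn) {
      v <- stats::rlnorm(length(genes), meanlog, sdlog)
      names(v) <- genes
      if (length(low_genes) > 0L) {
        q <- stats::runif(length(low_genes), 0, 0.05)
        v[low_genes] <- stats::qlnorm(q, meanlog, sdlog)
      }
      expression_profile(cn, v)
    })
    stats::setNames(out, conditions)
  })
}

#' Generate synthetic gene-level differential statistics
#'
#' Null genes get p ~ Uniform(0, 1) with a random direction. Genes in the
#' neighborhoods of the \code{hot_metabolites} get small p-values drawn as
#' \code{rbeta(shape, 1) * scale} (defaults give a median around 0.002)
#' with a shared "up" direction -- a coherent transcriptional signal
#' around those metabolites.
#'
#' @param model a \code{metabolic_model}.
#' @param hot_metabolites metabolite ids to plant a signal on.
#' @param effect list with \code{shape} and \code{scale} of the planted
#'   p-value distribution.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_id}, \code{p_value},
#'   \code{direction}.
#' @export
generate_gene_stats <- function(model, hot_metabolites = character(0),
                                effect = list(shape = 0.5, scale = 0.01),
                                seed = 1) {
  stopifnot(inherits(model, "metabolic_model"))
  genes <- model$genes
  nb <- build_neighborhoods(model)
  missing <- setdiff(hot_metabolites, model$metabolites$id)
  if (length(missing) > 0L)
    stop(sprintf("hot metabolite '%s' not in model", missing[1]))
  hot_genes <- unique(unlist(nb[intersect(hot_metabolites, names(nb))]))
  with_seed(seed, {
    p <- stats::runif(length(genes))
    dir <- sample(c("up", "down"), length(genes), replace = TRUE)
    hot <- genes %in% hot_genes
    if (any(hot)) {
      p[hot] <- pmax(stats::rbeta(sum(hot), effect$shape, 1) * effect$scale,
                     1e-12)
      dir[hot] <- "up"
    }
    data.frame(gene_id = genes, p_value = p, direction = dir,
               stringsAsFactors = FALSE)
  })
}

#' Write an FPKM profile list to the TSV format \code{read_fpkm} reads
#'
#' @param profiles named list of \code{expression_profile} sharing one
#'   gene universe.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_fpkm <- function(profiles, path) {
  genes <- names(profiles[[1]]$values)
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (p in profiles) tab[[p$condition]] <- unname(p$values[genes])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene statistics to TSV
#'
#' @param gene_stats data.frame with \code{gene_id}, \code{p_value},
#'   \code{direction}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_gene_stats <- function(gene_stats, path) {
  utils::write.table(gene_stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene statistics from TSV
#'
#' @param path TSV with columns \code{gene_id}, \code{p_value},
#'   \code{direction}.
#' @return data.frame.
#' @export
read_gene_stats <- function(path) {
  if (!file.exists(path)) stop(sprintf("gene stats file '%s' does not exist", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "p_value", "direction")
  if (!all(need %in% names(tab)))
    stop("gene stats TSV must have columns gene_id, p_value, direction")
  tab
}
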