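#' Directional Z-score for one gene
#'
#' Converts a two-sided gene-level p-value with a known direction of
#' change into a one-tailed Z-score for a chosen direction of interest:
#' the one-tailed p is p/2 when the gene moved in the direction of
#' interest and 1 - p/2 otherwise, and Z is the standard normal quantile
#' of its complement. This is the distinct-directional scoring used by
#' gene-set frameworks: genes moving with the direction of interest get
#' positive Z, genes moving against it negative Z.
#'
#' @param p_value two-sided p-value in (0, 1].
#' @param direction observed direction of change, \code{"up"} or
#'   \code{"down"}.
#' @param direction_of_interest direction being scored.
#' @return a finite Z-score (p is clamped to [1e-300, 1 - 1e-16] before
#'   inversion).
#' @examples
#' gene_zscore(0.05, "up", "up")     # ~1.96
#' gene_zscore(0.01, "down", "up")   # ~-2.58
#' @export
gene_zscore <- function(p_value, direction = c("up", "down"),
                        direction_of_interest = c("up", "down")) {
  direction <- match.arg(direction)
  direction_of_interest <- match.arg(direction_of_interest)
  if (!is.numeric(p_value) || p_value <= 0 || p_value > 1)
    stop("p-value must lie in (0, 1]")
  p_dir <- if (direction == direction_of_interest) p_value / 2 else 1 - p_value / 2
  p_dir <- min(max(p_dir, 1e-300), 1 - 1e-16)
  stats::qnorm(p_dir, lower.tail = FALSE)
}

#' Gene neighborhoods of metabolites
#'
#' For every metabolite, collects the union of GPR genes over all
#' reactions that consume or produce it (nonzero stoichiometric
#' coefficient). Metabolites touched only by GPR-less reactions are not
#' scorable and are omitted.
#'
#' @param model a \code{metabolic_model}.
#' @param exclude character vector of metabolite ids to skip (e.g.
#'   currency metabolites); default none.
#' @return named list mapping metabolite id to a character vector of gene
#'   ids.
#' @export
build_neighborhoods <- function(model, exclude = character(0)) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- model$stoichiometry
  rxn_genes <- lapply(model$reactions$gpr, function(g)
    if (is.na(g) || !nzchar(g)) character(0) else gpr_genes(parse_gpr(g)))
  out <- list()
  for (j in seq_len(nrow(S))) {
    mid <- rownames(S)[j]
    if (mid %in% exclude) next
    touching <- which(S[j, ] != 0)
    genes <- sort(unique(unlist(rxn_genes[touching])))
    if (length(genes) > 0L) out[[mid]] <- genes
  }
  out
}

#' Background moments for size-k gene sets
#'
#' Mean and standard deviation of the raw neighborhood score
#' \eqn{\sum Z / \sqrt{k}} over random size-k subsets of the scored gene
#' universe. Enumerated exhaustively when the number of subsets is at most
#' \code{exhaustive_limit}, otherwise estimated from \code{n_samples}
#' random subsets (without replacement within each subset).
#'
#' @param z numeric vector of gene Z-scores (the universe).
#' @param k subset size.
#' @param n_samples number of sampled subsets.
#' @param method \code{"auto"}, \code{"sample"} or \code{"exhaustive"}.
#' @param exhaustive_limit enumerate exhaustively when
#'   \code{choose(length(z), k)} is at most this.
#' @return list with \code{mu}, \code{sigma}, \code{method}.
#' @export
background_stats <- function(z, k, n_samples = 10000,
                             method = c("auto", "sample", "exhaustive"),
                             exhaustive_limit = 1e5) {
  method <- match.arg(method)
  n <- length(z)
  if (k > n) stop("neighborhood size exceeds the scored-gene universe")
  use_exh <- method == "exhaustive" ||
    (method == "auto" && choose(n, k) <= exhaustive_limit)
  if (use_exh) {
    sums <- utils::combn(n, k, FUN = function(ix) sum(z[ix]))
    scores <- sums / sqrt(k)
    return(list(mu = mean(scores),
                sigma = stats::sd(scores) * sqrt((length(scores) - 1) / length(scores)),
                method = "exhaustive"))
  }
  sums <- vapply(seq_len(n_samples),
                 function(i) sum(z[sample.int(n, k)]), numeric(1))
  scores <- sums / sqrt(k)
  list(mu = mean(scores),
       sigma = stats::sd(scores) * sqrt((n_samples - 1) / n_samples),
       method = "sample")
}

#' Reporter metabolite scores
#'
#' Aggregates directional gene Z-scores over each metabolite's gene
#' neighborhood, corrects against the background of random same-size gene
#' sets, and converts to upper-tail p-values:
#' \deqn{Z_{raw}(m) = \sum_{g \in G(m)} Z_g / \sqrt{k},\quad
#'       Z_{corr}(m) = (Z_{raw}(m) - \mu_k) / \sigma_k,\quad
#'       p = 1 - \Phi(Z_{corr}(m)).}
#' Both directions are scored from the same inputs (the down-direction
#' gene Z is the negation of the up-direction one) using the same sampled
#' background subsets, so results are reproducible from the seed alone.
#'
#' @param neighborhoods named list from \code{\link{build_neighborhoods}}.
#' @param gene_stats data.frame with columns \code{gene_id},
#'   \code{p_value} (two-sided, in (0, 1]), \code{direction}
#'   (\code{"up"}/\code{"down"}).
#' @param n_samples background subsets per neighborhood size.
#' @param seed integer seed driving the background sampling.
#' @param sigma_floor lower bound on the background standard deviation.
#' @param background \code{"auto"}, \code{"sample"} or \code{"exhaustive"}
#'   (see \code{\link{background_stats}}).
#' @return a \code{reporter_result} data.frame with one row per scorable
#'   metabolite: \code{metabolite_id}, \code{k}, \code{z_raw_up},
#'   \code{z_corrected_up}, \code{p_up}, \code{z_raw_down},
#'   \code{z_corrected_down}, \code{p_down}.
#' @export
reporter_scores <- function(neighborhoods, gene_stats, n_samples = 10000,
                            seed = 1, sigma_floor = 1e-12,
                            background = c("auto", "sample", "exhaustive")) {
  background <- match.arg(background)
  if (anyDuplicated(gene_stats$gene_id))
    stop("duplicate gene in gene_stats")
  if (any(gene_stats$p_value <= 0 | gene_stats$p_value > 1))
    stop("gene p-values must lie in (0, 1]")
  if (!all(gene_stats$direction %in% c("up", "down")))
    stop("gene direction must be 'up' or 'down'")

  z_up <- vapply(seq_len(nrow(gene_stats)), function(i)
    gene_zscore(gene_stats$p_value[i], gene_stats$direction[i], "up"),
    numeric(1))
  names(z_up) <- gene_stats$gene_id
  scored <- names(z_up)

  keep <- vapply(neighborhoods, function(g) length(intersect(g, scored)) >= 1L,
                 logical(1))
  nb <- neighborhoods[keep]
  if (length(nb) == 0L)
    stop("no metabolite neighborhood intersects the scored genes")
  gsets <- lapply(nb, intersect, y = scored)
  k <- vapply(gsets, length, integer(1))
  if (any(k > length(scored)))
    stop("neighborhood size exceeds the scored-gene universe")

  raw_up <- vapply(gsets, function(g) sum(z_up[g]) / sqrt(length(g)),
                   numeric(1))
  raw_down <- -raw_up

  bg <- list()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (kk in sort(unique(k)))
    bg[[as.character(kk)]] <- background_stats(z_up, kk, n_samples,
                                               method = background)
  mu <- vapply(as.character(k), function(s) bg[[s]]$mu, numeric(1))
  sg <- pmax(vapply(as.character(k), function(s) bg[[s]]$sigma, numeric(1)),
             sigma_floor)

  zc_up <- (raw_up - mu) / sg
  zc_down <- (raw_down - (-mu)) / sg  # the mirrored background
  structure(data.frame(
    metabolite_id = names(nb),
    k = k,
    z_raw_up = unname(raw_up),
    z_corrected_up = unname(zc_up),
    p_up = stats::pnorm(unname(zc_up), lower.tail = FALSE),
    z_raw_down = unname(raw_down),
    z_corrected_down = unname(zc_down),
    p_down = stats::pnorm(unname(zc_down), lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("reporter_result", "data.frame"))
}

#' Significant reporter metabolites
#'
#' Calls metabolites whose distinct-directional p-value falls below alpha,
#' separately per direction; no multiplicity correction is applied (the
#' plain p < alpha rule).
#'
#' @param result a \code{reporter_result}.
#' @param alpha significance level; default 0.05.
#' @return list with character vectors \code{up} and \code{down}.
#' @export
significant_reporters <- function(result, alpha = 0.05) {
  list(up = result$metabolite_id[result$p_up < alpha],
       down = result$metabolite_id[result$p_down < alpha])
}

#' Bipartite subnetwork induced by significant reporter metabolites
#'
#' @param model a \code{metabolic_model}.
#' @param significant_ids metabolite ids.
#' @return data.frame edge list with columns \code{metabolite_id},
#'   \code{reaction_id} (one row per incidence).
#' @export
reporter_subnetwork <- function(model, significant_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  missing <- setdiff(significant_ids, model$metabolites$id)
  if (length(missing) > 0L)
    stop(sprintf("metabolite '%s' not in model", missing[1]))
  S <- model$stoichiometry
  edges <- lapply(significant_ids, function(mid) {
    rids <- colnames(S)[S[mid, ] != 0]
    if (length(rids) == 0L) return(NULL)
    data.frame(metabolite_id = mid, reaction_id = rids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, edges)
  if (is.null(out))
    out <- data.frame(metabolite_id = character(0),
                      reaction_id = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
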