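#' Read a pipeline run configuration
#'
#' A run configuration holds every tunable of the end-to-end flow:
#' model and expression paths, the per-condition carbon source and uptake
#' rate, the expression percentile, the growth fraction, tolerances, the
#' significance level and the seed.
#'
#' @param path YAML file; see \code{\link{run_pipeline}} for the fields.
#' @return a named list (the parsed config).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  yaml::read_yaml(path)
}

#' Run the full transcriptome-integration pipeline
#'
#' Orchestrates model loading, per-condition FBA and GIMME, active-reaction
#' comparison across conditions, pathway classification of the combined
#' active set, and (when gene statistics are supplied) reporter-metabolite
#' identification. All tables are written under \code{output_dir} and a
#' machine-readable JSON manifest summarizes the run.
#'
#' @param config a list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{model_path, model_dialect}{model location; dialect
#'       \code{"sbml_fbc"} or \code{"tsv"}.}
#'     \item{fpkm_path}{FPKM TSV with one column per condition.}
#'     \item{gene_stats_path}{optional gene statistics TSV; the reporter
#'       stage is skipped when absent.}
#'     \item{conditions}{character vector of condition labels matching
#'       FPKM columns.}
#'     \item{carbon}{named list: condition -> list(exchange, rate).}
#'     \item{open_nutrients}{exchange ids left unconstrained.}
#'     \item{percentile}{expression threshold percentile (default 50).}
#'     \item{growth_fraction}{GIMME growth floor fraction (default 0.9).}
#'     \item{zero_tolerance}{active-reaction flux cutoff (default 1e-6).}
#'     \item{alpha}{reporter significance level (default 0.05).}
#'     \item{seed}{integer seed for the reporter background (default 1).}
#'     \item{output_dir}{where outputs are written.}
#'   }
#' @return the manifest list, invisibly; side effect: per-condition flux
#'   and penalty TSVs, venn/pathway/reporter tables and
#'   \code{manifest.json} under \code{output_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  defaults <- list(model_dialect = "sbml_fbc", percentile = 50,
                   growth_fraction = 0.9, zero_tolerance = 1e-6,
                   alpha = 0.05, seed = 1, open_nutrients = character(0),
                   gene_stats_path = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("model_path", "fpkm_path", "conditions", "carbon",
               "output_dir"))
    if (is.null(config[[nm]]))
      stop(sprintf("pipeline config is missing '%s'", nm))
  for (cn in config$conditions)
    if (is.null(config$carbon[[cn]]))
      stop(sprintf("condition '%s' has no carbon entry", cn))

  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  model <- stage("model_io",
                 read_model(config$model_path, config$model_dialect))
  profiles <- stage("expression", read_fpkm(config$fpkm_path))
  missing_cond <- setdiff(config$conditions, names(profiles))
  if (length(missing_cond) > 0L)
    stop(sprintf("pipeline stage 'expression' failed: FPKM table lacks condition '%s'",
                 missing_cond[1]))

  manifest <- list(config = config,
                   census = unclass(census(model)),
                   conditions = list())
  active_sets <- list()

  for (cn in config$conditions) {
    carbon <- config$carbon[[cn]]
    m_cond <- stage(paste0("uptake:", cn), apply_uptake(
      model,
      constraints = list(uptake_constraint(carbon$exchange, carbon$rate)),
      open_nutrients = unlist(config$open_nutrients)))
    profile <- profiles[[cn]]
    thr <- stage(paste0("threshold:", cn),
                 compute_threshold(profile, model,
                                   percentile = config$percentile))
    rxn_expr <- map_expression(model, profile)
    pen <- compute_penalties(rxn_expr, thr)
    sol <- stage(paste0("gimme:", cn), solve_gimme(
      m_cond, pen,
      gimme_config(config$growth_fraction, config$zero_tolerance)))
    if (sol$status != "optimal")
      stop(sprintf("pipeline stage 'gimme:%s' failed: solver status %s",
                   cn, sol$status))
    act <- active_reactions(sol, config$zero_tolerance)
    active_sets[[cn]] <- act

    utils::write.table(
      data.frame(reaction_id = names(sol$fluxes), flux = unname(sol$fluxes)),
      file.path(out_dir, paste0("fluxes_", cn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(reaction_id = names(pen), penalty = unname(pen)),
      file.path(out_dir, paste0("penalties_", cn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)

    manifest$conditions[[cn]] <- list(
      x_threshold = thr,
      fba_maximum = sol$fba_maximum,
      growth_rate = sol$growth_rate,
      inconsistency_score = sol$inconsistency_score,
      n_active = length(act))
  }

  if (length(config$conditions) >= 2L) {
    a <- config$conditions[1]; b <- config$conditions[2]
    venn <- compare_conditions(active_sets[[a]], active_sets[[b]])
    manifest$venn <- list(condition_a = a, condition_b = b,
                          only_a = length(venn$only_a),
                          only_b = length(venn$only_b),
                          core = length(venn$core),
                          union_size = venn$union_size)
    union_set <- sort(unique(unlist(active_sets)))
    pw <- classify_by_pathway(model, union_set)
    manifest$pathways <- c(as.list(pw$counts),
                           list(unclassified = pw$unclassified))
    utils::write.table(
      data.frame(reaction_id = union_set,
                 in_a = union_set %in% active_sets[[a]],
                 in_b = union_set %in% active_sets[[b]]),
      file.path(out_dir, "active_reactions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$gene_stats_path)) {
    stats_tab <- stage("reporter", read_gene_stats(config$gene_stats_path))
    nb <- build_neighborhoods(model)
    rep_res <- stage("reporter",
                     reporter_scores(nb, stats_tab, seed = config$seed))
    sig <- significant_reporters(rep_res, config$alpha)
    utils::write.table(rep_res, file.path(out_dir, "reporter_metabolites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$reporter <- list(n_scored = nrow(rep_res),
                              n_significant_up = length(sig$up),
                              n_significant_down = length(sig$down))
  }

  manifest$version <- as.character(utils::packageVersion("tigsmm"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
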