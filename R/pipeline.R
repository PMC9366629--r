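# Stage drivers tying the modules into the workflow
# (simulate -> filter -> score -> search -> hypotheses -> compare).
# Every output file embeds the global seed and a config hash; identical
# config + inputs reproduce byte-identical outputs. The numbered scripts
# under analysis/ are thin narrative wrappers over these functions.

#' Short stable hash of a configuration object
#' @param x any R object
#' @return 8-hex-digit string
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((h * 16777619) %% 4294967291 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

write_tsv_stamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by the pipeline (skipping the stamp line)
#' @param path file path
#' @return data.frame
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Stage: simulate a dataset to disk
#'
#' @param params a [sim_params()]
#' @param out_dir output directory
#' @param species_tree,taxon_table optional fixed inputs (see
#'   [simulate_dataset()])
#' @param quiet suppress the console summary?
#' @return the dataset, invisibly
#' @export
run_simulate <- function(params, out_dir, species_tree = NULL,
                         taxon_table = NULL, quiet = FALSE) {
  ds <- simulate_dataset(params, species_tree = species_tree,
                         taxon_table = taxon_table)
  write_dataset(ds, out_dir)
  if (!quiet) {
    cat(sprintf("simulated %d families on %d taxa (%d redraws)\n",
                params$n_families, ape::Ntip(ds$species_tree),
                sum(ds$truth$redraws)))
    cat(sprintf("mean observed copies per taxon: %.3f\n",
                mean(ds$truth$census)))
  }
  invisible(ds)
}

#' Stage: score a gene-tree set against a species tree
#'
#' Writes `family_report.tsv` (per-family duplications, losses, cost and
#' optimal rooting) and `score_summary.json`.
#' @param gene_trees path to a one-Newick-per-line file, or a named list of
#'   phylo objects
#' @param species_tree path to a Newick file, or a rooted binary phylo
#' @param out_dir output directory
#' @param weights a [cost_weights()]
#' @param loss_mode `"full"` or `"pruned"`
#' @param seed seed recorded in the outputs (scoring is deterministic)
#' @return list with `total` and `families` (as [total_cost()]), invisibly
#' @export
run_score <- function(gene_trees, species_tree, out_dir,
                      weights = cost_weights(), loss_mode = "full",
                      seed = 1L) {
  if (is.character(gene_trees)) gene_trees <- read_gene_trees(gene_trees)
  if (is.character(species_tree))
    species_tree <- read_newick(readLines(species_tree)[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- total_cost(gene_trees, species_tree, weights = weights,
                    loss_mode = loss_mode)
  hash <- config_hash(list(weights = weights, loss_mode = loss_mode))
  write_tsv_stamped(res$families, file.path(out_dir, "family_report.tsv"),
                    seed, hash)
  jsonlite::write_json(
    list(total_cost = res$total, n_families = nrow(res$families),
         dup_total = sum(res$families$dup_count),
         loss_total = sum(res$families$loss_count),
         loss_mode = loss_mode, seed = seed, config = hash),
    file.path(out_dir, "score_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Stage: replicated species-tree search
#'
#' Writes `replicates.tsv` (one row per replicate: seed, cost,
#' earliest-branching group, best tree) and `search_summary.json` (ranked
#' distinct topologies with frequencies and costs relative to the optimum).
#' @param gene_trees path or named list of phylo objects
#' @param config a [search_config()]
#' @param out_dir output directory
#' @param taxon_table optional [taxon_table()] (or path)
#' @return the [run_replicates()] result, invisibly
#' @export
run_search <- function(gene_trees, config, out_dir, taxon_table = NULL) {
  if (is.character(gene_trees)) gene_trees <- read_gene_trees(gene_trees)
  if (is.character(taxon_table)) taxon_table <- read_taxon_table(taxon_table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_replicates(gene_trees, config, taxon_table)
  hash <- config_hash(config[setdiff(names(config), "constraint")])
  write_tsv_stamped(res$records, file.path(out_dir, "replicates.tsv"),
                    config$seed, hash)
  jsonlite::write_json(
    list(seed = config$seed, config = hash,
         n_replicates = config$n_replicates,
         best_cost = res$best_cost,
         best_tree = canonical_newick(res$best_tree),
         topologies = lapply(seq_len(nrow(res$summary)), function(i)
           as.list(res$summary[i, ]))),
    file.path(out_dir, "search_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Stage: evaluate and compare root hypotheses
#'
#' Writes `costs.tsv` (replicate x hypothesis constrained costs) and
#' `comparison.tsv` (median, Shapiro-Wilk, Wilcoxon vs the reference,
#' significance at `alpha`). With fewer than 3 replicates the statistics are
#' skipped with a warning.
#' @param gene_trees path or named list of phylo objects
#' @param backbones list of [build_backbone()] objects
#' @param config a [search_config()]
#' @param taxon_table a [taxon_table()] (or path)
#' @param out_dir output directory
#' @param reference reference hypothesis id (default: lowest median)
#' @param alpha significance level
#' @return list with `cost_table` and `comparison` (NULL if skipped),
#'   invisibly
#' @export
run_hypotheses <- function(gene_trees, backbones, config, taxon_table,
                           out_dir, reference = NULL, alpha = 0.05) {
  if (is.character(gene_trees)) gene_trees <- read_gene_trees(gene_trees)
  if (is.character(taxon_table)) taxon_table <- read_taxon_table(taxon_table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct <- evaluate_hypotheses(gene_trees, backbones, config, taxon_table)
  hash <- config_hash(list(config[setdiff(names(config), "constraint")],
                           vapply(backbones, `[[`, character(1),
                                  "hypothesis_id")))
  cost_df <- data.frame(replicate_id = seq_len(nrow(ct)),
                        as.data.frame(unclass(ct)), check.names = FALSE)
  write_tsv_stamped(cost_df, file.path(out_dir, "costs.tsv"),
                    config$seed, hash)
  comparison <- NULL
  if (nrow(ct) >= 3L) {
    comparison <- compare_hypotheses(ct, reference = reference, alpha = alpha)
    write_tsv_stamped(as.data.frame(comparison),
                      file.path(out_dir, "comparison.tsv"),
                      config$seed, hash)
  } else {
    warning("fewer than 3 replicates: statistical comparison skipped")
  }
  invisible(list(cost_table = ct, comparison = comparison))
}
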