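# Replicable study-condition experiments: the package's own validation
# analyses. Each function runs one self-contained experiment at fixed
# conditions (sizes and rates chosen once as the simulation study design) and
# returns the measured quantities; the analysis/ scripts and the acceptance
# checks are thin callers.

#' Random small reconciliation instance
#'
#' A uniformly drawn species tree over at most `ns_max` taxa and a random
#' binary gene tree with multi-copy leaves over at most `ng_max` leaves.
#' @param seed integer seed
#' @param ns_max maximum species (3..ns_max drawn uniformly)
#' @param ng_max maximum gene leaves (3..ng_max drawn uniformly)
#' @param rooted return a rooted gene tree?
#' @return list with `sp` (species phylo) and `gene` (gene phylo)
#' @export
random_reconciliation_instance <- function(seed, ns_max = 5L, ng_max = 8L,
                                           rooted = TRUE) {
  with_seed(seed, {
    ns <- sample(3:ns_max, 1L)
    sp <- simulate_species_tree(ns, seed = derive_seed(seed, "sp"),
                                labels = LETTERS[1:ns])
    ng <- sample(3:ng_max, 1L)
    taxa <- sample(LETTERS[1:ns], ng, replace = TRUE)
    labs <- paste0(taxa, "|",
                   stats::ave(seq_along(taxa), taxa, FUN = seq_along))
    g <- ape::rtree(ng, tip.label = labs, br = NULL)
    if (!rooted && ng >= 3L) g <- ape::unroot(g)
    list(sp = sp, gene = g)
  })
}

#' Experiment: LCA cost versus the exhaustive-mapping oracle
#'
#' On `n_instances` random small instances, compares the LCA-based DL cost
#' with the minimum over all valid mappings.
#' @param n_instances number of instances
#' @param seed integer seed
#' @return list: `agreement_pct`, `n`
#' @export
experiment_reconciliation_check <- function(n_instances = 200L, seed = 1L) {
  ok <- vapply(seq_len(n_instances), function(i) {
    inst <- random_reconciliation_instance(derive_seed(seed, "recon", i))
    lca <- dl_events_and_losses(inst$gene, inst$sp)$cost
    lca == exhaustive_reconciliation_oracle(inst$gene, inst$sp)
  }, logical(1))
  list(agreement_pct = 100 * mean(ok), n = n_instances)
}

#' Experiment: the three worked reconciliation examples
#'
#' The single-duplication family, the missing-taxon family in full loss mode,
#' and the unrooted ac|bd family against a 4-taxon ladder, cross-checked
#' against brute force over all rootings.
#' @return list of the example counts and costs
#' @export
experiment_worked_examples <- function() {
  s3 <- read_newick("((A,B),C);")
  s4 <- read_newick("(((A,B),C),D);")
  r1 <- dl_events_and_losses(read_newick("(A|1,(A|2,B|1));"), s3)
  r2 <- dl_events_and_losses(read_newick("(A|1,C|1);"), s3, loss_mode = "full")
  gu <- read_newick("((A|1,C|1),(B|1,D|1));", rooted = FALSE)
  r3 <- dl_cost_unrooted(gu, s4)
  brute <- vapply(seq_len(nrow(gu$edge)), function(e)
    dl_events_and_losses(root_on_edge(gu, e), s4)$cost, numeric(1))
  list(dup_family_dups = r1$dup_count, dup_family_losses = r1$loss_count,
       missing_taxon_dups = r2$dup_count,
       missing_taxon_losses = r2$loss_count,
       unrooted_min_cost = r3$cost,
       unrooted_brute_force_min = min(brute),
       root_on_d_pendant = as.integer(r3$root_split == "D|1"))
}

#' Experiment: unrooted minimisation equals explicit per-edge scoring
#'
#' @param n_pairs number of random (gene tree, species tree) pairs
#' @param seed integer seed
#' @return list: `agreement_pct`, `n`
#' @export
experiment_unrooted_check <- function(n_pairs = 100L, seed = 1L) {
  ok <- vapply(seq_len(n_pairs), function(i) {
    inst <- random_reconciliation_instance(derive_seed(seed, "unroot", i),
                                           ns_max = 6L, ng_max = 9L,
                                           rooted = FALSE)
    if (ape::Ntip(inst$gene) < 3L) return(TRUE)
    got <- dl_cost_unrooted(inst$gene, inst$sp)$cost
    explicit <- min(vapply(seq_len(nrow(inst$gene$edge)), function(e)
      dl_events_and_losses(root_on_edge(inst$gene, e), inst$sp)$cost,
      numeric(1)))
    batched <- total_cost(list(g = inst$gene), inst$sp)$total
    got == explicit && batched == explicit
  }, logical(1))
  list(agreement_pct = 100 * mean(ok), n = n_pairs)
}

#' Experiment: heuristic search versus the exhaustive species-tree oracle
#'
#' Simulated datasets of 5-6 taxa and 20 families at moderate rates; a
#' 10-restart hill climb must reach the global optimum cost.
#' @param n_datasets number of datasets
#' @param seed integer seed
#' @param restarts restarts per dataset
#' @return list: `matches`, `n`
#' @export
experiment_search_oracle <- function(n_datasets = 20L, seed = 1L,
                                     restarts = 10L) {
  hits <- vapply(seq_len(n_datasets), function(i) {
    dseed <- derive_seed(seed, "oracle", i)
    n_taxa <- if (i %% 2L == 0L) 6L else 5L
    ds <- simulate_dataset(sim_params(n_taxa, 0.1, 0.1, 20L, seed = dseed))
    ex <- exhaustive_species_search(ds$gene_trees)
    cfg <- search_config(n_replicates = 1L, restarts = restarts,
                         seed = derive_seed(dseed, "search"))
    res <- run_replicates(ds$gene_trees, cfg, ds$taxon_table)
    res$best_cost == ex$best_cost
  }, logical(1))
  list(matches = sum(hits), n = n_datasets)
}

#' Experiment: recovery of the true rooted species tree
#'
#' For each seeded run, a fresh 8-taxon tree and 100 families at
#' dup = loss = 0.2 with complete sampling; success means the modal best
#' topology across the replicates is the true rooted tree.
#' @param n_runs independent seeded runs
#' @param n_replicates search replicates per run
#' @param seed integer seed
#' @return list: `successes`, `n`
#' @export
experiment_root_recovery <- function(n_runs = 10L, n_replicates = 10L,
                                     seed = 1L) {
  succ <- vapply(seq_len(n_runs), function(i) {
    rseed <- derive_seed(seed, "recovery", i)
    ds <- simulate_dataset(sim_params(8L, 0.2, 0.2, 100L, seed = rseed))
    cfg <- search_config(n_replicates = n_replicates,
                         seed = derive_seed(rseed, "search"))
    res <- run_replicates(ds$gene_trees, cfg, ds$taxon_table)
    modal <- res$summary$best_tree_newick[which.max(res$summary$frequency)]
    modal == canonical_newick(ds$species_tree)
  }, logical(1))
  list(successes = sum(succ), n = n_runs)
}

# the fixed three-clade design used by the missing-data experiment
artifact_design <- function() {
  taxa <- c(sprintf("bas%d", 1:3), sprintf("mid%d", 1:3), sprintf("red%d", 1:3))
  tab <- taxon_table(data.frame(
    taxon_id = taxa,
    major_clade = rep(c("Opisthokonta", "Amoebozoa", "SAR"), each = 3),
    minor_clade = rep(c("Fungi", "Tubulinea", "Ciliophora"), each = 3),
    source = rep(c("genome", "genome", "transcriptome"), each = 3),
    stringsAsFactors = FALSE))
  truth <- read_newick(paste0("((bas1,(bas2,bas3)),((mid1,(mid2,mid3)),",
                              "(red1,(red2,red3))));"))
  list(tab = tab, truth = truth, reduced = sprintf("red%d", 1:3))
}

#' Experiment: clade-biased missing data drags a clade to the root
#'
#' The missing-data/loss confound: under full-tree loss counting, an
#' under-sampled (low-retention) non-basal clade is pulled towards the root.
#' Two arms over the same true tree -- complete sampling versus retention
#' `retention` for one non-basal clade -- each searched with `n_replicates`
#' replicates; the measured quantity is the fraction of replicates placing
#' that clade (or part of it) as the earliest-branching group.
#' @param n_replicates replicates per arm
#' @param retention retention probability for the under-sampled clade
#' @param n_families families per arm
#' @param seed integer seed
#' @return list: `frac_control`, `frac_lowret`, `effect`, `increased`
#' @export
experiment_missing_data_artifact <- function(n_replicates = 20L,
                                             retention = 0.4,
                                             n_families = 100L, seed = 1L) {
  des <- artifact_design()
  arm <- function(ret, tag) {
    p <- sim_params(ape::Ntip(des$truth), 0.2, 0.2, n_families,
                    retention = ret, seed = derive_seed(seed, "arm", tag))
    ds <- simulate_dataset(p, species_tree = des$truth,
                           taxon_table = des$tab)
    cfg <- search_config(n_replicates = n_replicates,
                         seed = derive_seed(seed, "search", tag))
    res <- run_replicates(ds$gene_trees, cfg, des$tab)
    mean(vapply(res$trees, function(t)
      all(earliest_branching_group(t, des$tab)$taxa %in% des$reduced),
      logical(1)))
  }
  frac_control <- arm(1, "control")
  ret_map <- stats::setNames(rep(retention, length(des$reduced)),
                             des$reduced)
  frac_lowret <- arm(ret_map, "lowret")
  list(frac_control = frac_control, frac_lowret = frac_lowret,
       effect = frac_lowret - frac_control,
       increased = as.integer(frac_lowret > frac_control))
}

#' Experiment: discriminating root hypotheses on a planted-root simulation
#'
#' True tree rooted between Fungi and all other eukaryote clades of a
#' 10-taxon toy taxonomy; the five named backbones are evaluated with
#' constrained searches and compared by Wilcoxon rank-sum against the
#' fungal-root reference.
#' @param n_replicates replicates per hypothesis
#' @param n_families simulated families
#' @param seed integer seed
#' @param alpha significance level
#' @return list: `true_lowest_median`, `n_wrong`, `n_flagged`, `comparison`,
#'   `cost_table`
#' @export
experiment_hypothesis_discrimination <- function(n_replicates = 20L,
                                                 n_families = 60L,
                                                 seed = 1L, alpha = 0.05) {
  tab <- taxon_table(data.frame(
    taxon_id = c("fun1", "fun2", "met1", "met2", "amo1", "amo2",
                 "dis1", "dis2", "mem1", "anc1"),
    major_clade = c(rep("Opisthokonta", 4), rep("Amoebozoa", 2),
                    rep("Excavata", 3), "Orphan"),
    minor_clade = c("Fungi", "Fungi", "Metazoa", "Metazoa",
                    "Tubulinea", "Tubulinea",
                    "Discoba", "Discoba", "Metamonada", "Ancyromonadida"),
    source = "genome", stringsAsFactors = FALSE))
  truth <- read_newick(paste0(
    "((fun1,fun2),(((met1,met2),(amo1,amo2)),",
    "((dis1,dis2),(mem1,anc1))));"))
  ds <- simulate_dataset(sim_params(10L, 0.2, 0.2, n_families,
                                    seed = derive_seed(seed, "plant")),
                         species_tree = truth, taxon_table = tab)
  hyps <- c("fungi_others", "opisthokonta_others", "discoba_others",
            "unikonta_bikonta", "ancyromonadida_metamonada_others")
  bbs <- lapply(hyps, build_backbone, tab = tab)
  cfg <- search_config(n_replicates = n_replicates,
                       seed = derive_seed(seed, "hyp"))
  ct <- evaluate_hypotheses(ds$gene_trees, bbs, cfg, tab)
  cmp <- compare_hypotheses(ct, reference = "fungi_others", alpha = alpha)
  meds <- attr(ct, "medians")
  list(true_lowest_median = as.integer(which.min(meds) ==
                                         which(hyps == "fungi_others")),
       n_wrong = length(hyps) - 1L,
       n_flagged = sum(cmp$significant),
       comparison = cmp, cost_table = ct)
}
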