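# Heuristic search for the minimum-total-DL-cost rooted species tree, with
# rooted NNI/SPR moves (SPR includes regrafting onto the root edge, i.e. root
# relocation), stepwise-addition random starts, backbone constraints, an
# exhaustive small-n oracle, and the replicated randomisation protocol
# (shuffled gene order and leaf orders per replicate).
#
# The scorer here is order-invariant by construction, so shuffles cannot
# change any cost; they are still performed and logged for fidelity to the
# replication protocol, and replicate-to-replicate variation comes from the
# seeded random starts and tie-breaks.

#' Search configuration
#'
#' @param n_replicates number of independent replicates (protocol default 100)
#' @param moves `"spr"` (rooted SPR, includes root relocation; default) or
#'   `"nni"` (rooted NNI, faster, smaller neighbourhood)
#' @param restarts hill climbs per replicate, best kept
#' @param max_iterations cap on accepted moves per climb
#' @param weights a [cost_weights()]
#' @param loss_mode `"full"` or `"pruned"`
#' @param seed global seed; per-replicate seeds are derived from it
#' @param constraint optional [build_backbone()] result
#' @param subsample gene trees used by the greedy starting tree
#' @return a `search_config` object
#' @export
search_config <- function(n_replicates = 100L, moves = c("spr", "nni"),
                          restarts = 1L, max_iterations = 100L,
                          weights = cost_weights(),
                          loss_mode = c("full", "pruned"), seed = 1L,
                          constraint = NULL, subsample = 20L) {
  moves <- match.arg(moves)
  loss_mode <- match.arg(loss_mode)
  stopifnot(n_replicates >= 1, restarts >= 1, max_iterations >= 1)
  if (!is.null(constraint) && !inherits(constraint, "backbone"))
    stop("constraint must be a backbone object")
  structure(list(n_replicates = as.integer(n_replicates), moves = moves,
                 restarts = as.integer(restarts),
                 max_iterations = as.integer(max_iterations),
                 weights = weights, loss_mode = loss_mode,
                 seed = as.integer(seed), constraint = constraint,
                 subsample = as.integer(subsample)),
            class = "search_config")
}

# ---- clist editing ----------------------------------------------------------

extract_cl <- function(cl, path) {
  for (i in path) cl <- cl[[i]]
  cl
}

remove_cl <- function(cl, path) {
  if (length(path) == 1L) {
    rest <- cl[-path[1]]
    if (length(rest) == 1L) return(rest[[1]])
    return(rest)
  }
  cl[[path[1]]] <- remove_cl(cl[[path[1]]], path[-1])
  cl
}

replace_cl <- function(cl, path, sub) {
  if (!length(path)) return(sub)
  cl[[path[1]]] <- replace_cl(cl[[path[1]]], path[-1], sub)
  cl
}

clade_keys_cl <- function(cl) {
  out <- character(0)
  rec <- function(x) {
    if (is.character(x)) return(x)
    lv <- unlist(lapply(x, rec), use.names = FALSE)
    out[[length(out) + 1L]] <<- paste(sort(lv), collapse = ",")
    lv
  }
  rec(cl)
  out
}

constraint_ok_cl <- function(cl, backbone) {
  if (is.null(backbone)) return(TRUE)
  keys <- clade_keys_cl(cl)
  all(backbone$required_keys %in% c(keys,
        vapply(clist_leaves(cl), identity, character(1))))
}

spr_neighbors_cl <- function(cl) {
  out <- list()
  paths <- clist_paths(cl)
  for (p in paths) {
    sub <- extract_cl(cl, p)
    rem <- remove_cl(cl, p)
    if (is.character(rem)) next
    for (q in clist_paths(rem))
      out[[length(out) + 1L]] <- attach_at(rem, q, sub)
    out[[length(out) + 1L]] <- list(rem, sub)  # regraft on the root edge
  }
  out
}

nni_neighbors_cl <- function(cl) {
  out <- list()
  for (p in clist_paths(cl)) {
    v <- extract_cl(cl, p)
    if (is.character(v)) next
    parent_path <- p[-length(p)]
    sib <- extract_cl(cl, c(parent_path, 3L - p[length(p)]))
    for (i in 1:2) {
      newpar <- list(list(v[[3L - i]], sib), v[[i]])
      out[[length(out) + 1L]] <- replace_cl(cl, parent_path, newpar)
    }
  }
  out
}

# distinct neighbours (canonical-form dedup, original excluded), sorted by
# canonical string for reproducible tie-breaking
neighbors_cl <- function(cl, moves, constraint = NULL) {
  raw <- if (moves == "spr") spr_neighbors_cl(cl) else nni_neighbors_cl(cl)
  keys <- vapply(raw, canonical_newick, character(1))
  self <- canonical_newick(cl)
  keep <- !duplicated(keys) & keys != self
  raw <- raw[keep]; keys <- keys[keep]
  ord <- order(keys)
  raw <- raw[ord]
  if (!is.null(constraint))
    raw <- Filter(function(x) constraint_ok_cl(x, constraint), raw)
  raw
}

#' All species trees one rearrangement away
#'
#' @param tree rooted binary phylo
#' @param moves `"spr"` or `"nni"`
#' @param constraint optional [build_backbone()]; inconsistent trees are
#'   dropped
#' @return list of phylo objects (distinct topologies, original excluded)
#' @export
tree_neighbors <- function(tree, moves = c("spr", "nni"), constraint = NULL) {
  moves <- match.arg(moves)
  lapply(neighbors_cl(phylo_to_clist(tree), moves, constraint), clist_to_phylo)
}

# ---- scoring ----------------------------------------------------------------

score_clist <- function(cl, prep, weights, loss_mode) {
  sum(score_prepared(prep, sp_arrays_clist(cl, prep$taxa),
                     weights, loss_mode)$cost)
}

#' Total cost of a species tree for prepared families
#' @keywords internal
score_species_tree <- function(tree, prep, weights = cost_weights(),
                               loss_mode = "full") {
  score_clist(phylo_to_clist(tree), prep, weights, loss_mode)
}

# ---- starting trees ---------------------------------------------------------

random_topology_cl <- function(taxa) {
  if (length(taxa) == 1L) return(taxa)
  ord <- sample(taxa)
  if (length(ord) == 2L) return(list(ord[1], ord[2]))
  cl <- list(ord[1], ord[2])
  for (k in 3:length(ord)) {
    paths <- clist_paths(cl)
    pick <- sample.int(length(paths) + 1L, 1L)
    cl <- if (pick > length(paths)) list(cl, ord[k]) else
      attach_at(cl, paths[[pick]], ord[k])
  }
  cl
}

prune_gene_tree <- function(tree, taxa_set) {
  keep <- which(leaf_taxon(tree$tip.label) %in% taxa_set)
  if (length(keep) < 3L) return(NULL)
  pr <- ape::keep.tip(tree, keep)
  pr$edge.length <- NULL
  if (ape::is.rooted(pr) && ape::Ntip(pr) > 2L) pr <- ape::unroot(pr)
  pr
}

#' Greedy stepwise-addition starting tree
#'
#' Taxa are inserted in seeded random order, each at the attachment point
#' (including above the current root) minimising the total DL cost over a
#' random subsample of the gene trees, restricted at each stage to the taxa
#' already placed. With a constraint, a random constraint-consistent topology
#' is built instead (groups resolved randomly, joined per the backbone).
#'
#' @param taxa character vector of species (>= 3)
#' @param gene_trees named list of phylo objects
#' @param seed integer seed
#' @param subsample number of gene trees scored during insertion
#' @param weights a [cost_weights()]
#' @param loss_mode `"full"` or `"pruned"`
#' @param constraint optional [build_backbone()]
#' @return rooted binary phylo over `taxa`
#' @export
random_start_tree <- function(taxa, gene_trees, seed, subsample = 20L,
                              weights = cost_weights(), loss_mode = "full",
                              constraint = NULL) {
  stopifnot(length(taxa) >= 3L)
  with_seed(seed, {
    if (!is.null(constraint)) {
      cl <- backbone_random_cl(constraint, taxa)
      return(clist_to_phylo(cl))
    }
    fams <- gene_trees[sample.int(length(gene_trees),
                                  min(subsample, length(gene_trees)))]
    ord <- sample(taxa)
    cands3 <- list(list(list(ord[1], ord[2]), ord[3]),
                   list(list(ord[1], ord[3]), ord[2]),
                   list(list(ord[2], ord[3]), ord[1]))
    cl <- best_by_cost(cands3, fams, ord[1:3], weights, loss_mode)
    for (k in seq_along(ord)[-(1:3)]) {
      leaf <- ord[k]
      paths <- clist_paths(cl)
      cands <- c(lapply(paths, function(p) attach_at(cl, p, leaf)),
                 list(list(cl, leaf)))
      cl <- best_by_cost(cands, fams, ord[1:k], weights, loss_mode)
    }
    clist_to_phylo(cl)
  })
}

best_by_cost <- function(cands, fams, taxa_set, weights, loss_mode) {
  pruned <- Filter(Negate(is.null), lapply(fams, prune_gene_tree,
                                           taxa_set = taxa_set))
  if (!length(pruned)) {
    return(cands[[sample.int(length(cands), 1L)]])
  }
  prep <- prepare_families(pruned, taxa = taxa_set)
  costs <- vapply(cands, score_clist, numeric(1), prep = prep,
                  weights = weights, loss_mode = loss_mode)
  hits <- which(costs == min(costs))
  cands[[hits[sample.int(length(hits), 1L)]]]
}

# random constraint-consistent topology: resolve each backbone group and each
# backbone multifurcation randomly
backbone_random_cl <- function(backbone, taxa) {
  grp <- backbone$groups
  used <- unlist(grp, use.names = FALSE)
  extra <- setdiff(taxa, used)
  if (length(extra))
    stop("backbone does not cover taxa: ", paste(extra, collapse = ", "))
  build <- function(node) {
    if (is.character(node)) {
      sub <- random_topology_cl(grp[[node]])
      return(sub)
    }
    parts <- lapply(node, build)
    while (length(parts) > 2L) {
      i <- sort(sample.int(length(parts), 2L))
      parts[[i[1]]] <- list(parts[[i[1]]], parts[[i[2]]])
      parts[[i[2]]] <- NULL
    }
    if (length(parts) == 1L) parts[[1]] else parts
  }
  build(backbone$topology)
}

# ---- hill climbing ----------------------------------------------------------

#' Best-improvement hill climb over species-tree space
#'
#' Evaluates all neighbours under the configured move set, moves to the strict
#' best (seeded random tie-break among equals) and stops at a local optimum or
#' the iteration cap. The accepted-cost sequence is strictly decreasing.
#'
#' @param gene_trees named list of phylo objects, or a `prepared_families`
#' @param start rooted binary phylo to start from
#' @param config a [search_config()]
#' @param seed seed for the tie-breaks (default derived from `config$seed`)
#' @return a `replicate_record`: `start_cost`, `best_tree`, `best_cost`,
#'   `iterations`, `converged`, `trajectory`
#' @export
hill_climb <- function(gene_trees, start, config, seed = NULL) {
  prep <- if (inherits(gene_trees, "prepared_families")) gene_trees
          else prepare_families(gene_trees)
  if (!setequal(prep$taxa, start$tip.label))
    stop("start tree must cover exactly the analysis taxa")
  if (is.null(seed)) seed <- derive_seed(config$seed, "climb")
  cl <- phylo_to_clist(start)
  if (!constraint_ok_cl(cl, config$constraint))
    stop("start tree violates the constraint")
  with_seed(seed, {
    cur_cost <- score_clist(cl, prep, config$weights, config$loss_mode)
    start_cost <- cur_cost
    traj <- cur_cost
    iter <- 0L
    converged <- FALSE
    repeat {
      if (iter >= config$max_iterations) break
      nbs <- neighbors_cl(cl, config$moves, config$constraint)
      if (!length(nbs)) { converged <- TRUE; break }
      costs <- vapply(nbs, score_clist, numeric(1), prep = prep,
                      weights = config$weights, loss_mode = config$loss_mode)
      if (min(costs) >= cur_cost) { converged <- TRUE; break }
      hits <- which(costs == min(costs))
      cl <- nbs[[hits[sample.int(length(hits), 1L)]]]
      cur_cost <- min(costs)
      traj <- c(traj, cur_cost)
      iter <- iter + 1L
    }
    structure(list(start_cost = start_cost, best_tree = clist_to_phylo(cl),
                   best_cost = cur_cost, iterations = iter,
                   converged = converged, trajectory = traj, seed = seed),
              class = "replicate_record")
  })
}

#' Exhaustive search over all rooted binary species topologies
#'
#' Scores every rooted topology over the taxon set (enumerated with
#' [phangorn::allTrees]); the global-optimum oracle for small n.
#' @param gene_trees named list of phylo objects
#' @param taxa taxon set (default: union over families); at most 7
#' @param weights a [cost_weights()]
#' @param loss_mode `"full"` or `"pruned"`
#' @return list with `best_tree`, `best_cost`, `co_optima` (all optimal
#'   trees), `n_scored`
#' @export
exhaustive_species_search <- function(gene_trees, taxa = NULL,
                                      weights = cost_weights(),
                                      loss_mode = "full") {
  prep <- if (inherits(gene_trees, "prepared_families")) gene_trees
          else prepare_families(gene_trees)
  if (is.null(taxa)) taxa <- prep$taxa
  if (length(taxa) > 7L)
    stop("exhaustive search is limited to 7 taxa (10,395 rooted topologies)")
  trees <- phangorn::allTrees(length(taxa), rooted = TRUE, tip.label = taxa)
  costs <- vapply(trees, function(tr)
    score_clist(phylo_to_clist(tr), prep, weights, loss_mode), numeric(1))
  hits <- which(costs == min(costs))
  list(best_tree = trees[[hits[1]]], best_cost = min(costs),
       co_optima = trees[hits], n_scored = length(trees))
}

# ---- replicates -------------------------------------------------------------

#' Earliest-branching group at the root of a species tree
#'
#' The smaller root-child clade (ties broken towards the side with the
#' alphabetically smallest taxon), summarised by the minimal covering clade
#' label from the taxon table.
#' @param tree rooted binary phylo
#' @param tab a [taxon_table()]
#' @return list with `taxa` and `label`
#' @export
earliest_branching_group <- function(tree, tab) {
  cl <- phylo_to_clist(tree)
  sides <- lapply(cl, clist_leaves)
  pick <- if (length(sides[[1]]) != length(sides[[2]]))
    which.min(lengths(sides))
  else if (min(sides[[1]]) <= min(sides[[2]])) 1L else 2L
  list(taxa = sort(sides[[pick]]),
       label = covering_clade_label(tab, sides[[pick]]))
}

#' Run the replicated randomised search
#'
#' Each replicate draws its own seed (from the global one), shuffles the gene
#' order and every gene tree's leaf order (protocol fidelity; the scorer is
#' order-invariant so costs cannot change), builds `restarts` random starting
#' trees, hill climbs from each, and keeps the best. The summary ranks the
#' distinct best topologies by cost, then frequency, with costs relative to
#' the replicate optimum.
#'
#' @param gene_trees named list of phylo objects
#' @param config a [search_config()]
#' @param taxon_table a [taxon_table()]; synthesised (single clade) if NULL
#' @return list with `records` (data.frame), `trees` (best phylo per
#'   replicate), `summary` (ranked topology table), `best_tree`, `best_cost`
#' @export
run_replicates <- function(gene_trees, config, taxon_table = NULL) {
  taxa <- sort(unique(unlist(lapply(gene_trees,
                                    function(g) leaf_taxon(g$tip.label)))))
  if (is.null(taxon_table))
    taxon_table <- taxon_table(data.frame(
      taxon_id = taxa, major_clade = "Orphan", minor_clade = "unassigned",
      source = "unknown", stringsAsFactors = FALSE))
  recs <- vector("list", config$n_replicates)
  trees <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    rseed <- derive_seed(config$seed, "replicate", r)
    perm <- with_seed(derive_seed(rseed, "geneorder"),
                      sample.int(length(gene_trees)))
    shuffled <- lapply(seq_along(perm), function(i)
      shuffle_leaf_order(gene_trees[[perm[i]]], derive_seed(rseed, "leaf", i)))
    names(shuffled) <- names(gene_trees)[perm]
    prep <- prepare_families(shuffled, taxa = taxa)
    best <- NULL
    for (s in seq_len(config$restarts)) {
      start <- random_start_tree(taxa, shuffled,
                                 seed = derive_seed(rseed, "start", s),
                                 subsample = config$subsample,
                                 weights = config$weights,
                                 loss_mode = config$loss_mode,
                                 constraint = config$constraint)
      rec <- hill_climb(prep, start, config,
                        seed = derive_seed(rseed, "climb", s))
      if (is.null(best) || rec$best_cost < best$best_cost) best <- rec
    }
    ebg <- earliest_branching_group(best$best_tree, taxon_table)
    recs[[r]] <- data.frame(
      replicate_id = r, seed = rseed, start_cost = best$start_cost,
      total_cost = best$best_cost, iterations = best$iterations,
      converged = best$converged, earliest_branching_group = ebg$label,
      best_tree_newick = canonical_newick(best$best_tree),
      stringsAsFactors = FALSE)
    trees[[r]] <- best$best_tree
  }
  records <- do.call(rbind, recs)
  agg <- stats::aggregate(records["total_cost"],
                          by = records["best_tree_newick"], FUN = min)
  freq <- table(records$best_tree_newick)
  agg$frequency <- as.integer(freq[agg$best_tree_newick])
  agg <- agg[order(agg$total_cost, -agg$frequency, agg$best_tree_newick), ]
  agg$relative_cost <- agg$total_cost / min(agg$total_cost)
  rownames(agg) <- NULL
  i_best <- which.min(records$total_cost)
  list(records = records, trees = trees, summary = agg,
       best_tree = trees[[i_best]], best_cost = records$total_cost[i_best])
}
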