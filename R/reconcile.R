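# Duplication-loss reconciliation under LCA mapping.
#
# Conventions (the classic gene-tree-parsimony DL criterion):
#   * every gene node maps to the LCA, in the species tree, of the taxa below;
#   * an internal gene node is a duplication iff its mapping equals the
#     mapping of at least one child, otherwise a speciation;
#   * each gene-tree edge (p -> c) contributes d - 1 losses if p is a
#     speciation and d if p is a duplication, with d the number of species
#     edges between map(p) and map(c);
#   * no losses are charged above the mapping of the gene root;
#   * an unrooted gene tree is scored at its cost-optimal rooting over all
#     2n - 3 edges.
#
# Two engines implement this: a readable pure-R path (reference; used for the
# per-node event reports) and a batched C++ path (used by the species-tree
# search). Tests assert their agreement instance-by-instance, and both against
# an exhaustive enumeration over all valid mappings.

#' Duplication/loss cost weights
#' @param dup,loss non-negative weights (default 1 each, the plain
#'   duplication-loss criterion)
#' @return a `cost_weights` object
#' @export
cost_weights <- function(dup = 1, loss = 1) {
  if (!is.numeric(dup) || !is.numeric(loss) || dup < 0 || loss < 0)
    stop("weights must be non-negative numbers")
  if (dup == 0 && loss == 0) stop("weights must not both be zero")
  structure(list(dup = dup, loss = loss), class = "cost_weights")
}

# pruned-depth vector over species nodes: number of nodes on the root->v path
# (inclusive) that survive restriction to `present` taxa with suppression of
# degree-2 nodes; with present = all tips this reduces to depth + 1.
pruned_depths <- function(spidx, present) {
  nn <- spidx$nnode
  inp <- logical(nn)
  cnt <- integer(nn)
  cnt[spidx$tip_of[present]] <- 1L
  kidpos <- integer(nn)
  for (v in spidx$postorder) {
    p <- spidx$parent[v]
    if (p > 0L && cnt[v] > 0L) {
      cnt[p] <- cnt[p] + cnt[v]
      kidpos[p] <- kidpos[p] + 1L
    }
  }
  inp <- (seq_len(nn) <= spidx$ntip & cnt > 0L) | kidpos >= 2L
  pd <- integer(nn)
  for (v in rev(spidx$postorder)) {
    p <- spidx$parent[v]
    pd[v] <- (if (p > 0L) pd[p] else 0L) + (if (inp[v]) 1L else 0L)
  }
  pd
}

#' LCA mapping of a rooted gene tree onto a species tree
#'
#' @param gene rooted phylo; leaf labels `taxon|copy` (or bare taxon ids)
#' @param species_tree rooted binary phylo
#' @return integer vector over gene nodes (ape numbering) giving the species
#'   node each gene node maps to
#' @export
lca_map <- function(gene, species_tree) {
  spidx <- species_index(species_tree)
  lca_map_idx(gene, spidx)
}

lca_map_idx <- function(gene, spidx) {
  ntip <- ape::Ntip(gene)
  nn <- ntip + gene$Nnode
  mapping <- integer(nn)
  taxa <- leaf_taxon(gene$tip.label)
  sp_tip <- spidx$tip_of[taxa]
  if (anyNA(sp_tip))
    stop("gene-tree taxa absent from species tree: ",
         paste(unique(taxa[is.na(sp_tip)]), collapse = ", "))
  mapping[seq_len(ntip)] <- sp_tip
  for (i in ape::postorder(gene)) {
    p <- gene$edge[i, 1]; c <- gene$edge[i, 2]
    mapping[p] <- if (mapping[p] == 0L) mapping[c]
                  else lca_pair(mapping[p], mapping[c], spidx$parent, spidx$depth)
  }
  mapping
}

#' Reconcile a rooted gene tree against a rooted species tree
#'
#' Reference (pure-R) DL reconciliation: LCA mapping, per-node event labels,
#' loss counting and the weighted cost.
#'
#' @param gene rooted phylo (binary; a two-leaf cherry is allowed)
#' @param species_tree rooted binary phylo
#' @param weights a [cost_weights()] object
#' @param loss_mode `"full"` charges losses on the whole species tree, so taxa
#'   absent from the family register as losses (missing data and true loss are
#'   indistinguishable, as in the rooting analyses this package supports);
#'   `"pruned"` first restricts the species tree to the family's taxon set.
#' @param family_id optional id carried into the result
#' @return a `reconciliation` object: mapping, events, `dup_count`,
#'   `loss_count`, `cost`
#' @export
dl_events_and_losses <- function(gene, species_tree, weights = cost_weights(),
                                 loss_mode = c("full", "pruned"),
                                 family_id = NULL) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(inherits(weights, "cost_weights"))
  spidx <- species_index(species_tree)
  mapping <- lca_map_idx(gene, spidx)
  ntip <- ape::Ntip(gene)
  nn <- ntip + gene$Nnode
  pd <- pruned_depths(spidx,
                      if (loss_mode == "pruned")
                        unique(leaf_taxon(gene$tip.label))
                      else species_tree$tip.label)
  kids <- split(gene$edge[, 2], gene$edge[, 1])
  events <- rep(NA_character_, nn)
  dup_count <- 0L
  for (p in unique(gene$edge[, 1])) {
    ch <- kids[[as.character(p)]]
    dup <- any(mapping[ch] == mapping[p])
    events[p] <- if (dup) "duplication" else "speciation"
    if (dup) dup_count <- dup_count + 1L
  }
  loss_count <- 0L
  for (i in seq_len(nrow(gene$edge))) {
    p <- gene$edge[i, 1]; c <- gene$edge[i, 2]
    d <- pd[mapping[c]] - pd[mapping[p]]
    loss_count <- loss_count + d - (if (events[p] == "speciation") 1L else 0L)
  }
  structure(list(family_id = family_id, mapping = mapping, events = events,
                 dup_count = dup_count, loss_count = as.integer(loss_count),
                 cost = weights$dup * dup_count + weights$loss * loss_count,
                 loss_mode = loss_mode, weights = weights, root_edge = NA),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("DL reconciliation", if (!is.null(x$family_id)) paste0("[", x$family_id, "]"),
      "\n  duplications:", x$dup_count, " losses:", x$loss_count,
      " cost:", x$cost, " (loss_mode=", x$loss_mode, ")\n", sep = "")
  invisible(x)
}

# ---- rooting an unrooted gene tree -----------------------------------------

# adjacency list of a phylo (ignoring stored orientation)
phylo_adj <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Root an unrooted gene tree on one of its edges
#' @param tree unrooted phylo
#' @param edge_index row of `tree$edge` to place the root on
#' @return rooted phylo
#' @export
root_on_edge <- function(tree, edge_index) {
  adj <- phylo_adj(tree)
  ntip <- ape::Ntip(tree)
  sub <- function(v, from) {
    nb <- setdiff(adj[[v]], from)
    if (v <= ntip) return(tree$tip.label[v])
    lapply(nb, sub, from = v)
  }
  u <- tree$edge[edge_index, 1]; v <- tree$edge[edge_index, 2]
  clist_to_phylo(list(sub(u, v), sub(v, u)))
}

# canonical per-edge keys: sorted leaf labels of the side not containing the
# alphabetically smallest leaf (lexicographic tie-break order for rootings)
edge_bipartition_keys <- function(tree) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  below <- below_sets(tree)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    side <- below[[tree$edge[i, 2]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = ",")
  }, character(1))
}

#' Minimum DL cost of an unrooted gene tree over all rootings
#'
#' Scores a root placed on every edge and returns the minimum-cost
#' reconciliation together with the winning edge. Ties are broken
#' deterministically by the lexicographic order of the edges' leaf-label
#' bipartitions.
#'
#' @inheritParams dl_events_and_losses
#' @param gene unrooted binary phylo with at least 3 leaves
#' @return a `reconciliation` with `root_edge` (edge index into `gene$edge`)
#'   and `root_split` (the bipartition key) set
#' @export
dl_cost_unrooted <- function(gene, species_tree, weights = cost_weights(),
                             loss_mode = c("full", "pruned"), family_id = NULL) {
  loss_mode <- match.arg(loss_mode)
  if (ape::Ntip(gene) < 3L) stop("unrooted gene tree needs >= 3 leaves")
  if (ape::is.rooted(gene)) gene <- ape::unroot(gene)
  keys <- edge_bipartition_keys(gene)
  best <- NULL
  for (e in order(keys)) {
    rec <- dl_events_and_losses(root_on_edge(gene, e), species_tree,
                                weights = weights, loss_mode = loss_mode,
                                family_id = family_id)
    if (is.null(best) || rec$cost < best$cost) {
      best <- rec
      best$root_edge <- e
      best$root_split <- keys[e]
    }
  }
  best
}

# ---- batched scoring (C++ engine) ------------------------------------------

#' Prepare gene families for repeated scoring
#'
#' Precomputes, once per family, the arrays the C++ scorer needs, so that many
#' candidate species trees can be scored cheaply during search.
#' @param gene_trees named list of phylo objects (rooted or unrooted)
#' @param taxa character vector fixing the taxon index space (defaults to the
#'   union of taxa seen in the families)
#' @return a `prepared_families` list
#' @export
prepare_families <- function(gene_trees, taxa = NULL) {
  if (!length(gene_trees)) stop("empty gene-tree collection")
  if (is.null(names(gene_trees)))
    names(gene_trees) <- sprintf("gf%04d", seq_along(gene_trees))
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(gene_trees,
                                      function(g) leaf_taxon(g$tip.label)))))
  fams <- lapply(gene_trees, function(g) {
    ntip <- ape::Ntip(g)
    nn <- ntip + g$Nnode
    tip_taxon <- integer(nn)
    tx <- match(leaf_taxon(g$tip.label), taxa)
    if (anyNA(tx))
      stop("gene-tree taxa outside the taxon space: ",
           paste(unique(leaf_taxon(g$tip.label)[is.na(tx)]), collapse = ", "))
    tip_taxon[seq_len(ntip)] <- tx
    rooted <- ape::is.rooted(g)
    nbrs <- split(c(g$edge[, 2], g$edge[, 1]), c(g$edge[, 1], g$edge[, 2]))
    adj <- integer(0)
    adj_start <- integer(nn + 1L)
    adj_start[1] <- 1L
    for (v in seq_len(nn)) {
      nv <- nbrs[[as.character(v)]]
      adj <- c(adj, nv)
      adj_start[v + 1L] <- adj_start[v] + length(nv)
    }
    list(edge = g$edge, nnode = nn, tip_taxon = tip_taxon, rooted = rooted,
         root = ntip + 1L, adj = adj, adj_start = adj_start,
         edge_order = if (rooted) seq_len(nrow(g$edge))
                      else order(edge_bipartition_keys(g)))
  })
  flat <- list(
    nnode = vapply(fams, `[[`, integer(1), "nnode"),
    rooted = vapply(fams, function(f) as.integer(f$rooted), integer(1)),
    root = vapply(fams, `[[`, integer(1), "root"),
    tip_flat = unlist(lapply(fams, `[[`, "tip_taxon"), use.names = FALSE),
    adj_flat = unlist(lapply(fams, `[[`, "adj"), use.names = FALSE),
    adjst_flat = unlist(lapply(fams, `[[`, "adj_start"), use.names = FALSE),
    e1 = unlist(lapply(fams, function(f) f$edge[, 1]), use.names = FALSE),
    e2 = unlist(lapply(fams, function(f) f$edge[, 2]), use.names = FALSE),
    n_edge = vapply(fams, function(f) nrow(f$edge), integer(1)),
    eord_flat = unlist(lapply(fams, `[[`, "edge_order"), use.names = FALSE))
  structure(list(fams = fams, flat = flat, taxa = taxa,
                 ids = names(gene_trees)),
            class = "prepared_families")
}

# species arrays for the C++ scorer, from a phylo over (a superset of) `taxa`
sp_arrays_phylo <- function(species_tree, taxa) {
  spidx <- species_index(species_tree)
  taxon_sp <- unname(spidx$tip_of[taxa])
  list(parent = spidx$parent, depth = spidx$depth,
       postorder = spidx$postorder, taxon_sp = taxon_sp)
}

# species arrays straight from a nested-list tree (search hot path)
sp_arrays_clist <- function(cl, taxa) {
  n <- length(taxa)
  env <- new.env()
  env$parent <- integer(2L * n)
  env$depth <- integer(2L * n)
  env$post <- integer(0)
  env$next_id <- n
  rec <- function(x, dep) {
    if (is.character(x)) {
      id <- match(x, taxa)
      env$depth[id] <- dep
      env$post <- c(env$post, id)
      return(id)
    }
    env$next_id <- env$next_id + 1L
    id <- env$next_id
    env$depth[id] <- dep
    for (ch in x) {
      k <- rec(ch, dep + 1L)
      env$parent[k] <- id
    }
    env$post <- c(env$post, id)
    id
  }
  root <- rec(cl, 0L)
  keep <- seq_len(env$next_id)
  list(parent = env$parent[keep], depth = env$depth[keep],
       postorder = env$post, taxon_sp = seq_len(n))
}

score_prepared <- function(prep, sp_arr, weights, loss_mode) {
  fl <- prep$flat
  dl_score_batch_cpp(fl$nnode, fl$rooted, fl$root, fl$tip_flat, fl$adj_flat,
                     fl$adjst_flat, fl$e1, fl$e2, fl$n_edge, fl$eord_flat,
                     sp_arr$parent, sp_arr$depth, sp_arr$postorder,
                     sp_arr$taxon_sp, weights$dup, weights$loss,
                     loss_mode == "pruned")
}

#' Total DL cost of a gene-tree collection against a species tree
#'
#' Sums the per-family minimum costs (unrooted families are scored at their
#' optimal rooting). Invariant to gene order and to leaf-order shuffles.
#'
#' @param gene_trees named list of phylo objects, or a `prepared_families`
#' @param species_tree rooted binary phylo covering all family taxa
#' @param weights a [cost_weights()]
#' @param loss_mode `"full"` or `"pruned"` (see [dl_events_and_losses()])
#' @param engine `"cpp"` (batched, default) or `"r"` (reference path)
#' @return list with `total` and a per-family data.frame `families`
#'   (`family_id`, `dup_count`, `loss_count`, `cost`, `root_split`,
#'   `loss_mode`)
#' @export
total_cost <- function(gene_trees, species_tree, weights = cost_weights(),
                       loss_mode = c("full", "pruned"),
                       engine = c("cpp", "r")) {
  loss_mode <- match.arg(loss_mode)
  engine <- match.arg(engine)
  if (inherits(gene_trees, "prepared_families")) {
    prep <- gene_trees
    if (engine == "r") stop("the reference engine needs the phylo list itself")
    trees <- NULL
  } else {
    if (!length(gene_trees)) stop("empty gene-tree collection")
    trees <- gene_trees
    prep <- prepare_families(gene_trees)
  }
  missing_tx <- setdiff(prep$taxa, species_tree$tip.label)
  if (length(missing_tx))
    stop("gene-tree taxa absent from species tree: ",
         paste(missing_tx, collapse = ", "))
  if (engine == "cpp") {
    sp_arr <- sp_arrays_phylo(species_tree, prep$taxa)
    res <- score_prepared(prep, sp_arr, weights, loss_mode)
    split_of <- vapply(seq_along(prep$fams), function(i) {
      f <- prep$fams[[i]]
      if (f$rooted || is.null(trees)) return(NA_character_)
      edge_bipartition_keys(trees[[i]])[res$root_edge[i]]
    }, character(1))
    fam_df <- data.frame(family_id = prep$ids, dup_count = res$dups,
                         loss_count = res$losses, cost = res$cost,
                         root_split = split_of, loss_mode = loss_mode,
                         stringsAsFactors = FALSE)
  } else {
    recs <- lapply(seq_along(trees), function(i) {
      g <- trees[[i]]
      if (ape::is.rooted(g))
        dl_events_and_losses(g, species_tree, weights, loss_mode,
                             family_id = prep$ids[i])
      else
        dl_cost_unrooted(g, species_tree, weights, loss_mode,
                         family_id = prep$ids[i])
    })
    fam_df <- data.frame(family_id = prep$ids,
                         dup_count = vapply(recs, `[[`, integer(1), "dup_count"),
                         loss_count = vapply(recs, `[[`, integer(1), "loss_count"),
                         cost = vapply(recs, `[[`, numeric(1), "cost"),
                         root_split = vapply(recs, function(r)
                           if (is.null(r$root_split)) NA_character_ else r$root_split,
                           character(1)),
                         loss_mode = loss_mode, stringsAsFactors = FALSE)
  }
  list(total = sum(fam_df$cost), families = fam_df)
}

# ---- exhaustive oracle ------------------------------------------------------

#' Exhaustive minimum DL cost over all valid gene-to-species mappings
#'
#' Test oracle, independent of the LCA construction: enumerates every mapping
#' that sends each internal gene node to an ancestor-or-self of its subtree's
#' LCA (respecting ancestry along gene edges), labels events and counts losses
#' as path stretch, and returns the minimum weighted cost. By the classic
#' optimality result this must equal the LCA-based cost.
#'
#' @param gene rooted phylo, at most 8 leaves
#' @param species_tree rooted binary phylo, at most 7 leaves
#' @param weights a [cost_weights()]
#' @return minimum cost (numeric)
#' @export
exhaustive_reconciliation_oracle <- function(gene, species_tree,
                                             weights = cost_weights()) {
  if (ape::Ntip(species_tree) > 7L || ape::Ntip(gene) > 8L)
    stop("instance too large for the exhaustive oracle")
  spidx <- species_index(species_tree)
  lmap <- lca_map_idx(gene, spidx)
  ntip <- ape::Ntip(gene)
  nn <- ntip + gene$Nnode
  kids <- split(gene$edge[, 2], gene$edge[, 1])
  internal <- sort(unique(gene$edge[, 1]))
  ancestors_of <- function(v) {
    out <- v
    while (spidx$parent[v] > 0L) { v <- spidx$parent[v]; out <- c(out, v) }
    out
  }
  cand <- lapply(seq_len(nn), function(v)
    if (v <= ntip) lmap[v] else ancestors_of(lmap[v]))
  is_anc <- function(a, d) {  # a ancestor-or-equal of d?
    while (spidx$depth[d] > spidx$depth[a]) d <- spidx$parent[d]
    a == d
  }
  # gene internal nodes in postorder (children decided before parents)
  post_int <- unique(gene$edge[ape::postorder(gene), 1])
  M <- lmap
  best <- Inf
  score_assignment <- function() {
    dups <- 0L; losses <- 0L
    ev <- rep(NA, nn)
    for (p in internal) {
      ch <- kids[[as.character(p)]]
      l <- Reduce(function(a, b) lca_pair(a, b, spidx$parent, spidx$depth), M[ch])
      spec <- (M[p] == l) && all(M[ch] != M[p])
      ev[p] <- !spec
      if (!spec) dups <- dups + 1L
    }
    for (i in seq_len(nrow(gene$edge))) {
      p <- gene$edge[i, 1]; c <- gene$edge[i, 2]
      d <- spidx$depth[M[c]] - spidx$depth[M[p]]
      losses <- losses + d - (if (ev[p]) 0L else 1L)
    }
    weights$dup * dups + weights$loss * losses
  }
  recurse <- function(k) {
    if (k > length(post_int)) {
      s <- score_assignment()
      if (s < best) best <<- s
      return(invisible())
    }
    p <- post_int[k]
    ch <- kids[[as.character(p)]]
    for (m in cand[[p]]) {
      if (all(vapply(ch, function(c) is_anc(m, M[c]), logical(1)))) {
        M[p] <<- m
        recurse(k + 1L)
      }
    }
    M[p] <<- lmap[p]
  }
  recurse(1L)
  best
}
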