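# Gene-family simulator: a branch-wise duplication-loss process on a known
# rooted species tree, with leaf-level retention (clade-biased missing data)
# and optional NNI noise. Ground truth (every duplication, loss and unsampled
# copy, with its species branch) is logged so that emitted trees can be
# replayed from the log and reconciliation estimates compared to the truth.
#
# Model: one gene lineage enters the species root. Along each species branch
# every entering lineage acquires Poisson(dup_rate) duplications (sequential
# random splitting among its copies), then each resulting copy survives with
# probability exp(-loss_rate). At a species leaf each surviving copy is
# observed with probability retention[taxon]; unobserved copies are logged as
# "unsampled", distinguishable from true losses in the log but not to the
# reconciler -- the missing-data/loss confound under study. Expected observed
# copies per taxon: retention * ((1 + dup_rate) * exp(-loss_rate))^depth.

#' Simulation parameters
#'
#' @param n_taxa number of species (>= 3)
#' @param dup_rate expected duplications per gene lineage per species branch
#' @param loss_rate per-branch loss hazard; each copy survives a branch with
#'   probability `exp(-loss_rate)`
#' @param n_families number of gene families to emit
#' @param retention probability an extant copy at a species leaf is observed:
#'   a single number, or a named vector by taxon (missing taxa default to 1)
#' @param noise_nni number of random NNI perturbations applied to each
#'   emitted gene tree (0 = none)
#' @param seed integer seed; the whole dataset is deterministic given it
#' @return a `sim_params` object
#' @export
sim_params <- function(n_taxa, dup_rate = 0.2, loss_rate = 0.2,
                       n_families = 100L, retention = 1, noise_nni = 0L,
                       seed = 1L) {
  stopifnot(n_taxa >= 3, n_families >= 1, noise_nni >= 0)
  if (!is.finite(dup_rate) || dup_rate < 0) stop("dup_rate must be finite and >= 0")
  if (!is.finite(loss_rate) || loss_rate < 0) stop("loss_rate must be finite and >= 0")
  if (any(retention < 0 | retention > 1)) stop("retention must lie in [0, 1]")
  structure(list(n_taxa = as.integer(n_taxa), dup_rate = dup_rate,
                 loss_rate = loss_rate, n_families = as.integer(n_families),
                 retention = retention, noise_nni = as.integer(noise_nni),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a uniformly random rooted binary species tree
#'
#' Sequential leaf insertion at a uniformly chosen attachment edge (including
#' the root edge) yields the uniform distribution over rooted binary
#' topologies.
#' @param n_taxa number of leaves (>= 3)
#' @param seed integer seed
#' @param labels leaf labels (default `T01`, `T02`, ...)
#' @return rooted binary phylo
#' @export
simulate_species_tree <- function(n_taxa, seed, labels = NULL) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (is.null(labels)) labels <- sprintf("T%02d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  with_seed(seed, {
    cl <- list(labels[1], labels[2])
    for (k in 3:n_taxa) {
      paths <- clist_paths(cl)          # one per non-root node
      pick <- sample(length(paths) + 1L, 1L)
      cl <- if (pick > length(paths)) list(cl, labels[k])
            else attach_at(cl, paths[[pick]], labels[k])
    }
    clist_to_phylo(cl)
  })
}

# paths (child-index vectors) to every non-root node of a clist
clist_paths <- function(cl) {
  out <- list()
  rec <- function(x, path) {
    for (i in seq_along(x)) {
      out[[length(out) + 1L]] <<- c(path, i)
      if (!is.character(x[[i]])) rec(x[[i]], c(path, i))
    }
  }
  if (!is.character(cl)) rec(cl, integer(0))
  out
}

# replace the node at `path` by a cherry (node, new leaf)
attach_at <- function(cl, path, leaf) {
  if (!length(path)) return(list(cl, leaf))
  cl[[path[1]]] <- attach_at(cl[[path[1]]], path[-1], leaf)
  cl
}

# ---- one family -------------------------------------------------------------

clade_key <- function(cl) paste(sort(clist_leaves(cl)), collapse = ",")

#' Simulate one gene family on a species tree
#'
#' Families with fewer than 3 observed leaves are discarded and redrawn under
#' a derived seed; the number of redraws is reported.
#' @param species_tree rooted binary phylo
#' @param params a [sim_params()] (its `n_taxa` is ignored in favour of the
#'   tree)
#' @param family_seed integer seed for this family
#' @param family_id id recorded in the truth log
#' @return list with `tree` (unrooted phylo), `events` (data.frame:
#'   `family_id`, `event`, `branch`, `lineage`, `new_lineage`), `census`
#'   (named copy counts per taxon), `n_redraws`, `seed_used`
#' @export
simulate_gene_family <- function(species_tree, params, family_seed,
                                 family_id = "gf0001") {
  sp_cl <- phylo_to_clist(species_tree)
  taxa <- species_tree$tip.label
  ret <- params$retention
  ret_of <- function(tx) {
    if (length(ret) == 1L && is.null(names(ret))) return(ret)
    if (!is.null(names(ret)) && tx %in% names(ret)) return(ret[[tx]])
    1
  }
  attempt <- 0L
  repeat {
    seed_used <- if (attempt == 0L) family_seed
                 else derive_seed(family_seed, "redraw", attempt)
    draw <- sim_family_draw(sp_cl, params, seed_used, ret_of)
    cl <- draw$cl
    env <- draw$env
    n_leaves <- if (is.null(cl)) 0L else length(clist_leaves(cl))
    if (n_leaves >= 3L) break
    attempt <- attempt + 1L
    if (attempt > 1000L) stop("family kept collapsing below 3 leaves; rates too extreme")
  }
  tree <- ape::unroot(clist_to_phylo(cl))
  ev <- if (length(env$rows))
    data.frame(family_id = family_id,
               event = vapply(env$rows, `[[`, character(1), "event"),
               branch = vapply(env$rows, `[[`, character(1), "branch"),
               lineage = vapply(env$rows, function(r) as.integer(r$lineage), integer(1)),
               new_lineage = vapply(env$rows, function(r) as.integer(r$new_lineage), integer(1)),
               stringsAsFactors = FALSE)
  else
    data.frame(family_id = character(0), event = character(0),
               branch = character(0), lineage = integer(0),
               new_lineage = integer(0), stringsAsFactors = FALSE)
  census <- table(factor(leaf_taxon(tree$tip.label), levels = taxa))
  list(tree = tree, events = ev,
       census = stats::setNames(as.integer(census), taxa),
       n_redraws = attempt, seed_used = seed_used, family_id = family_id)
}

# one draw of the branch process (no minimum-size redraw): returns the
# realised rooted clist (or NULL) plus the event-log environment
sim_family_draw <- function(sp_cl, params, seed, ret_of) {
    env <- new.env()
    env$next_id <- 2L
    env$rows <- list()
    log_ev <- function(event, branch, lineage, new_lineage = NA_integer_) {
      env$rows[[length(env$rows) + 1L]] <-
        list(event = event, branch = branch, lineage = lineage,
             new_lineage = new_lineage)
    }
    branch <- function(sp_sub, lineage) {
      b <- if (is.character(sp_sub)) sp_sub else clade_key(sp_sub)
      # duplications: sequential random splitting among this lineage's copies
      mini <- as.character(lineage)
      leaves <- lineage
      k <- stats::rpois(1L, params$dup_rate)
      for (j in seq_len(k)) {
        pick <- leaves[[sample.int(length(leaves), 1L)]]
        new_id <- env$next_id; env$next_id <- env$next_id + 1L
        log_ev("duplication", b, pick, new_id)
        mini <- split_id_leaf(mini, pick, new_id)
        leaves <- c(leaves, new_id)
      }
      # survival of each copy across the branch
      surv <- stats::runif(length(leaves)) < exp(-params$loss_rate)
      dead <- leaves[!surv]
      for (id in dead) log_ev("loss", b, id)
      leaves <- leaves[surv]
      if (!length(leaves)) return(NULL)
      mini <- drop_id_leaves(mini, as.character(dead))
      # continue each surviving copy below
      subst <- function(x) {
        if (is.character(x)) {
          id <- as.integer(x)
          if (is.character(sp_sub)) {            # species leaf: observation
            if (stats::runif(1L) < ret_of(sp_sub))
              return(paste0(sp_sub, "|", id))
            log_ev("unsampled", sp_sub, id)
            return(NULL)
          }
          l <- branch(sp_sub[[1]], id)
          r <- branch(sp_sub[[2]], id)
          if (is.null(l)) return(r)
          if (is.null(r)) return(l)
          return(list(l, r))
        }
        a <- subst(x[[1]]); b2 <- subst(x[[2]])
        if (is.null(a)) return(b2)
        if (is.null(b2)) return(a)
        list(a, b2)
      }
      subst(mini)
    }
    cl <- with_seed(seed, {
      l <- branch(sp_cl[[1]], 1L)
      r <- branch(sp_cl[[2]], 1L)
      if (is.null(l)) r else if (is.null(r)) l else list(l, r)
    })
  list(cl = cl, env = env)
}

# single raw draw of the process, no minimum-size redraw: the per-taxon
# observed-copy census (all-zero draws allowed); used to check the analytic
# expectation of the branch process without truncation bias
simulate_gene_family_raw <- function(species_tree, params, seed) {
  sp_cl <- phylo_to_clist(species_tree)
  ret <- params$retention
  ret_of <- function(tx) {
    if (length(ret) == 1L && is.null(names(ret))) return(ret)
    if (!is.null(names(ret)) && tx %in% names(ret)) return(ret[[tx]])
    1
  }
  draw <- sim_family_draw(sp_cl, params, seed, ret_of)
  taxa <- species_tree$tip.label
  if (is.null(draw$cl))
    return(stats::setNames(integer(length(taxa)), taxa))
  obs <- leaf_taxon(clist_leaves(draw$cl))
  census <- table(factor(obs, levels = taxa))
  stats::setNames(as.integer(census), taxa)
}

# mini-tree helpers over lineage-id clists (ids stored as character leaves)
split_id_leaf <- function(cl, id, new_id) {
  if (is.character(cl)) {
    if (cl == as.character(id)) return(list(as.character(id), as.character(new_id)))
    return(cl)
  }
  lapply(cl, split_id_leaf, id = id, new_id = new_id)
}

drop_id_leaves <- function(cl, dead) {
  if (is.character(cl)) return(if (cl %in% dead) NULL else cl)
  ch <- Filter(Negate(is.null), lapply(cl, drop_id_leaves, dead = dead))
  if (!length(ch)) return(NULL)
  if (length(ch) == 1L) return(ch[[1]])
  ch
}

#' Replay a family's truth log into its observed gene tree
#'
#' Deterministically reconstructs the observed rooted topology from the event
#' log alone; the emitted (unrooted) tree must be isomorphic to its unrooted
#' form. Used to validate log/tree consistency.
#' @param events one family's rows from the truth log
#' @param species_tree the species tree the family was simulated on
#' @return rooted phylo of observed copies (or NULL if none survive)
#' @export
replay_truth <- function(events, species_tree) {
  sp_cl <- phylo_to_clist(species_tree)
  branch <- function(sp_sub, lineage) {
    b <- if (is.character(sp_sub)) sp_sub else clade_key(sp_sub)
    rows <- events[events$branch == b, , drop = FALSE]
    mini <- as.character(lineage)
    leaves <- lineage
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$event == "duplication" && r$lineage %in% leaves) {
        mini <- split_id_leaf(mini, r$lineage, r$new_lineage)
        leaves <- c(leaves, r$new_lineage)
      }
    }
    dead <- rows$lineage[rows$event %in% c("loss", "unsampled")]
    dead <- dead[dead %in% leaves]
    mini <- drop_id_leaves(mini, as.character(dead))
    if (is.null(mini)) return(NULL)
    subst <- function(x) {
      if (is.character(x)) {
        id <- as.integer(x)
        if (is.character(sp_sub)) return(paste0(sp_sub, "|", id))
        l <- branch(sp_sub[[1]], id)
        r <- branch(sp_sub[[2]], id)
        if (is.null(l)) return(r)
        if (is.null(r)) return(l)
        return(list(l, r))
      }
      a <- subst(x[[1]]); b2 <- subst(x[[2]])
      if (is.null(a)) return(b2)
      if (is.null(b2)) return(a)
      list(a, b2)
    }
    subst(mini)
  }
  l <- branch(sp_cl[[1]], 1L)
  r <- branch(sp_cl[[2]], 1L)
  cl <- if (is.null(l)) r else if (is.null(r)) l else list(l, r)
  if (is.null(cl) || is.character(cl)) return(NULL)
  clist_to_phylo(cl)
}

#' Apply random NNI perturbations to an unrooted gene tree
#'
#' Emulates gene-tree estimation error. A 3-leaf tree has no internal edge;
#' requesting noise on one warns and returns the tree unchanged.
#' @param tree unrooted binary phylo
#' @param n_nni number of successive random NNIs
#' @param seed integer seed
#' @return perturbed phylo
#' @export
apply_noise <- function(tree, n_nni, seed) {
  if (n_nni == 0L) return(tree)
  if (ape::Ntip(tree) < 4L) {
    warning("tree has no internal edge; noise skipped")
    return(tree)
  }
  with_seed(seed, {
    for (i in seq_len(n_nni)) {
      nbs <- phangorn::nni(tree)
      tree <- nbs[[sample.int(length(nbs), 1L)]]
    }
    tree
  })
}

# ---- whole datasets ---------------------------------------------------------

#' Simulate a full gene-family dataset
#'
#' @param params a [sim_params()]
#' @param species_tree optional fixed true tree; drawn uniformly at random
#'   from `params` otherwise
#' @param taxon_table optional [taxon_table()]; a trivial single-clade table
#'   is synthesised when absent
#' @return list with `species_tree`, `gene_trees` (named list, unrooted),
#'   `truth` (`events` data.frame, `census` matrix taxa x families,
#'   `redraws`), `taxon_table`, `params`
#' @export
simulate_dataset <- function(params, species_tree = NULL, taxon_table = NULL) {
  seed <- params$seed
  if (is.null(species_tree))
    species_tree <- simulate_species_tree(params$n_taxa,
                                          derive_seed(seed, "sptree"))
  taxa <- species_tree$tip.label
  if (is.null(taxon_table))
    taxon_table <- taxon_table(data.frame(
      taxon_id = taxa, major_clade = "Orphan", minor_clade = "unassigned",
      source = "unknown", stringsAsFactors = FALSE))
  ids <- sprintf("gf%04d", seq_len(params$n_families))
  fams <- lapply(seq_len(params$n_families), function(i)
    simulate_gene_family(species_tree, params, derive_seed(seed, "fam", i),
                         family_id = ids[i]))
  trees <- lapply(fams, `[[`, "tree")
  names(trees) <- ids
  if (params$noise_nni > 0L)
    trees <- lapply(seq_along(trees), function(i)
      apply_noise(trees[[i]], params$noise_nni, derive_seed(seed, "noise", i)))
  names(trees) <- ids
  census <- do.call(cbind, lapply(fams, `[[`, "census"))
  colnames(census) <- ids
  list(species_tree = species_tree, gene_trees = trees,
       truth = list(events = do.call(rbind, lapply(fams, `[[`, "events")),
                    census = census,
                    redraws = vapply(fams, `[[`, integer(1), "n_redraws")),
       taxon_table = taxon_table, params = params)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `gene_trees.nwk` (one Newick per line), `taxa.tsv`,
#' `truth_events.tsv` and `params.json`. Re-running with the same seed
#' reproduces byte-identical files.
#' @param dataset result of [simulate_dataset()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the four file paths
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, c("gene_trees.nwk", "taxa.tsv",
                                "truth_events.tsv", "params.json"))
  write_gene_trees(dataset$gene_trees, paths[1])
  write_taxon_table(dataset$taxon_table, paths[2])
  utils::write.table(dataset$truth$events, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- dataset$params
  jsonlite::write_json(
    list(n_taxa = p$n_taxa, dup_rate = p$dup_rate, loss_rate = p$loss_rate,
         n_families = p$n_families,
         retention = if (is.null(names(p$retention))) p$retention
                     else as.list(p$retention),
         noise_nni = p$noise_nni, seed = p$seed,
         species_tree = write_newick(dataset$species_tree),
         redraws = sum(dataset$truth$redraws)),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
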