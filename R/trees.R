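#' @useDynLib gtproot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import ape
NULL

# ---- seeded RNG scope -------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers never disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a global seed and a stream label
#'
#' One global seed reproduces a whole run: every stage, replicate and family
#' draws its own stream through this hash. Kept below 2^31 - 1.
#' @param seed integer global seed
#' @param ... labels (coerced to character) identifying the stream
#' @return integer seed
#' @export
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((h * 16777619) %% 2147483629 + b) %% 2147483629
  as.integer(h %% 2147483587L + 1L)
}

# ---- Newick I/O -------------------------------------------------------------

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at position ", nchar(text))
  if (!grepl(";\\s*$", text)) stop("malformed Newick: missing terminal ';' at position ",
                                   nchar(text))
  invisible(TRUE)
}

#' Parse a Newick string into a rooted or unrooted tree
#'
#' Branch lengths and internal labels are accepted but discarded: every
#' analysis in this package is topology-only. When `rooted = FALSE` and the
#' string carries a two-child top-level bifurcation, the root is collapsed so
#' the returned tree is genuinely unrooted (degree-3 internal nodes).
#'
#' @param text a single Newick string
#' @param rooted logical; is a rooted tree expected?
#' @param binary logical; reject polytomies? (Species trees must be binary.)
#' @param resolve_seed if non-NULL and `binary = FALSE` input has polytomies,
#'   resolve them randomly with this seed instead of rejecting.
#' @return an [ape::phylo] object
#' @export
read_newick <- function(text, rooted = TRUE, binary = TRUE, resolve_seed = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  tr$edge.length <- NULL
  tr$node.label <- NULL
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label))) stop("malformed Newick: empty leaf label")
  if (!ape::is.binary(tr)) {
    if (!is.null(resolve_seed)) {
      tr <- with_seed(resolve_seed, ape::multi2di(tr, random = TRUE))
      tr$edge.length <- NULL
    } else if (binary) {
      stop("polytomy found but a binary tree is required")
    }
  }
  if (!rooted && ape::is.rooted(tr) && ape::Ntip(tr) > 2L) {
    tr <- ape::unroot(tr)
  }
  tr
}

#' Serialise a tree to Newick
#'
#' Round-trip safe: `read_newick(write_newick(t))` is isomorphic to `t`.
#' @param tree a phylo object
#' @return a Newick string
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Read a gene-tree set, one Newick per line
#'
#' Leaf labels follow the `taxon|copy` convention; single-copy leaves may omit
#' the `|copy` suffix. Trees are returned unrooted; polytomies are resolved
#' randomly under a seed derived per line from `resolve_seed`.
#'
#' @param path file path (one Newick per line), or NULL to use `lines`
#' @param lines character vector of Newick strings
#' @param family_ids optional ids; defaults to `gf0001`, `gf0002`, ...
#' @param resolve_seed seed for random resolution of gene-tree polytomies
#' @return a named list of unrooted phylo objects
#' @export
read_gene_trees <- function(path = NULL, lines = NULL, family_ids = NULL,
                            resolve_seed = 1L) {
  if (is.null(lines)) lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene trees found")
  if (is.null(family_ids)) family_ids <- sprintf("gf%04d", seq_along(lines))
  trees <- lapply(seq_along(lines), function(i)
    read_newick(lines[i], rooted = FALSE, binary = FALSE,
                resolve_seed = derive_seed(resolve_seed, "resolve", i)))
  names(trees) <- family_ids
  trees
}

#' Write a gene-tree set, one Newick per line
#' @param trees list of phylo objects
#' @param path output path
#' @export
write_gene_trees <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
}

# ---- leaf-label helpers -----------------------------------------------------

#' Taxon id of a gene-tree leaf label (`taxon|copy` -> `taxon`)
#' @param labels character vector of leaf labels
#' @return character vector of taxon ids
#' @export
leaf_taxon <- function(labels) sub("\\|.*$", "", labels)

# ---- nested-list (clist) representation ------------------------------------
# Internal rooted-tree representation used by the search moves and the
# simulator: a leaf is its label string, an internal node a list of children.

phylo_to_clist <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    lapply(kids[[as.character(node)]], build)
  }
  build(ntip + 1L)
}

clist_newick <- function(cl) {
  rec <- function(x) {
    if (is.character(x)) return(x)
    paste0("(", paste(vapply(x, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(cl), ";")
}

clist_to_phylo <- function(cl) ape::read.tree(text = clist_newick(cl))

clist_leaves <- function(cl) {
  if (is.character(cl)) return(cl)
  unlist(lapply(cl, clist_leaves), use.names = FALSE)
}

# Children sorted recursively by smallest leaf label: a canonical form whose
# Newick string identifies a rooted topology.
canonical_clist <- function(cl) {
  if (is.character(cl)) return(cl)
  ch <- lapply(cl, canonical_clist)
  key <- vapply(ch, function(x) min(clist_leaves(x)), character(1))
  ch[order(key)]
}

#' Canonical Newick string identifying a rooted topology
#'
#' Two rooted trees over the same leaves are isomorphic iff their canonical
#' strings are equal (children are sorted by smallest descendant label).
#' @param tree a rooted phylo object (or internal clist)
#' @return a Newick string
#' @export
canonical_newick <- function(tree) {
  cl <- if (inherits(tree, "phylo")) phylo_to_clist(tree) else tree
  clist_newick(canonical_clist(cl))
}

#' Splits (bipartitions) of an unrooted tree
#'
#' Each non-trivial edge yields a bipartition of the leaf set, encoded as the
#' sorted side not containing the alphabetically smallest leaf. Two unrooted
#' binary trees are isomorphic iff their split sets are equal.
#' @param tree a phylo object (rooted trees are unrooted first)
#' @param trivial include pendant (single-leaf) splits?
#' @return character vector of split keys
#' @export
unrooted_splits <- function(tree, trivial = FALSE) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  ntip <- ape::Ntip(tree)
  below <- below_sets(tree)
  keys <- vapply(seq_len(nrow(tree$edge)), function(i) {
    side <- below[[tree$edge[i, 2]]]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = ",")
  }, character(1))
  n_side <- lengths(strsplit(keys, ",", fixed = TRUE))
  keep <- rep(TRUE, length(keys))
  if (!trivial) keep <- n_side > 1L & n_side < ntip - 1L
  sort(unique(keys[keep & n_side < ntip]))
}

# list over all nodes: tip labels below each node (stored orientation)
below_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  ord <- rev(ape::postorder(tree))  # we need children before parents: postorder
  for (i in ape::postorder(tree)) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below
}

#' Test topological isomorphism of two trees
#' @param t1,t2 phylo objects
#' @param rooted compare as rooted (TRUE) or unrooted (FALSE) topologies
#' @return logical
#' @export
trees_isomorphic <- function(t1, t2, rooted = TRUE) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  if (rooted) canonical_newick(t1) == canonical_newick(t2)
  else identical(unrooted_splits(t1), unrooted_splits(t2))
}

# ---- leaf-order shuffling ---------------------------------------------------

#' Randomly permute child order at every node
#'
#' Reproduces the leaf-order shuffling protocol applied to input gene trees:
#' the Newick string changes, the topology (and thus every reconciliation
#' cost) does not.
#' @param tree a phylo object
#' @param seed integer seed; same seed, same output
#' @return a phylo object isomorphic to `tree`
#' @export
shuffle_leaf_order <- function(tree, seed) {
  cl <- phylo_to_clist(tree)
  shuf <- function(x) {
    if (is.character(x)) return(x)
    lapply(sample(length(x)), function(i) shuf(x[[i]]))
  }
  out <- with_seed(seed, shuf(cl))
  clist_to_phylo(out)
}

# ---- basic rooted-tree queries ---------------------------------------------

#' Index arrays for a rooted species tree
#'
#' Precomputes parent, depth and postorder arrays plus the tip-label lookup
#' used by the reconciliation engines.
#' @param tree rooted binary phylo
#' @return a list with `tree`, `parent`, `depth`, `postorder`, `tip_of`
#' @keywords internal
species_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be strictly binary")
  if (anyDuplicated(tree$tip.label)) stop("species tree has duplicate leaf labels")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- integer(nn)
  po <- integer(0)
  for (i in rev(ape::postorder(tree))) {  # parents before children
    e <- tree$edge[i, ]
    depth[e[2]] <- depth[e[1]] + 1L
  }
  # children-before-parents node sequence
  post_nodes <- c(tree$edge[ape::postorder(tree), 2], ntip + 1L)
  tip_of <- stats::setNames(seq_len(ntip), tree$tip.label)
  list(tree = tree, parent = parent, depth = depth,
       postorder = post_nodes, tip_of = tip_of, ntip = ntip, nnode = nn)
}

#' Most recent common ancestor of a taxon set
#' @param tree rooted phylo
#' @param taxa character vector of leaf labels (non-empty)
#' @return internal node id (ape numbering); for a single taxon, its tip id
#' @export
lca_node <- function(tree, taxa) {
  idx <- species_index(tree)
  unknown <- setdiff(taxa, names(idx$tip_of))
  if (!length(taxa)) stop("taxon set must be non-empty")
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  nodes <- idx$tip_of[taxa]
  Reduce(function(a, b) lca_pair(a, b, idx$parent, idx$depth), nodes)
}

lca_pair <- function(a, b, parent, depth) {
  while (depth[a] > depth[b]) a <- parent[a]
  while (depth[b] > depth[a]) b <- parent[b]
  while (a != b) { a <- parent[a]; b <- parent[b] }
  a
}

#' Edge-count distance from an ancestor down to a descendant
#' @param tree rooted phylo
#' @param ancestor,descendant node ids (ape numbering)
#' @return integer number of edges on the path
#' @export
node_depth_distance <- function(tree, ancestor, descendant) {
  idx <- species_index(tree)
  d <- 0L
  v <- descendant
  while (v != ancestor) {
    v <- idx$parent[v]
    d <- d + 1L
    if (v == 0L) stop("'ancestor' is not an ancestor of 'descendant'")
  }
  d
}
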