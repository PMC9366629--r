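# Gene-family selection: taxon/clade representation thresholds and the
# eukaryote-monophyly screen against interdomain lateral transfer and
# contamination. All filters are pure functions of a family census, so the
# surviving set never depends on input order.

#' Census of one gene family
#'
#' Copy counts per taxon plus clade rollups: which major clades are
#' represented, and which minor clades within each.
#' @param x an unrooted/rooted phylo with `taxon|copy` leaves, or a named
#'   integer vector of per-taxon copy counts
#' @param tab a [taxon_table()] resolving every taxon
#' @param family_id id carried into the census
#' @return a `family_census` object
#' @export
family_census <- function(x, tab, family_id = NULL) {
  if (inherits(x, "phylo")) {
    taxa <- leaf_taxon(x$tip.label)
    counts <- table(taxa)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- x[x > 0]
    if (!length(counts)) stop("empty family: no taxa with copies")
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (!length(counts)) stop("empty family: no taxa with copies")
  majors <- tt_lookup(tab, names(counts), "major_clade")
  minors <- tt_lookup(tab, names(counts), "minor_clade")
  minors_by_major <- lapply(split(minors, majors), unique)
  structure(list(family_id = family_id, counts = counts,
                 n_taxa = length(counts),
                 majors = sort(unique(majors)),
                 minors_by_major = minors_by_major,
                 minor_of = stats::setNames(minors, names(counts))),
            class = "family_census")
}

#' Number of taxa a census has in a given minor (or major) clade
#' @param census a [family_census()]
#' @param clade minor- or major-clade name
#' @param tab the [taxon_table()] used to build the census
#' @return integer count of distinct taxa
#' @export
clade_presence_count <- function(census, clade, tab) {
  taxa <- names(census$counts)
  minors <- tt_lookup(tab, taxa, "minor_clade")
  majors <- tt_lookup(tab, taxa, "major_clade")
  known <- clade %in% c(tab$minor_clade, tab$major_clade)
  if (!known) stop("unknown clade: ", clade)
  sum(minors == clade | majors == clade)
}

#' Selection policy for gene families
#'
#' Defaults encode the study's rule: at least 25 taxa, representing at least
#' 4 of the major clades, with at least 2 major clades contributing at least
#' 2 minor clades each.
#' @param min_taxa minimum distinct taxa
#' @param min_major_clades minimum major clades represented
#' @param min_majors_with_two_minors minimum major clades holding >= 2 minor
#'   clades
#' @return a `filter_policy` object
#' @export
filter_policy <- function(min_taxa = 25L, min_major_clades = 4L,
                          min_majors_with_two_minors = 2L) {
  stopifnot(min_taxa >= 1, min_major_clades >= 1,
            min_majors_with_two_minors >= 0)
  structure(list(min_taxa = as.integer(min_taxa),
                 min_major_clades = as.integer(min_major_clades),
                 min_majors_with_two_minors = as.integer(min_majors_with_two_minors)),
            class = "filter_policy")
}

#' Does a family pass the selection policy?
#'
#' A multi-copy taxon counts once: the thresholds speak of taxa, not
#' sequences.
#' @param census a [family_census()]
#' @param policy a [filter_policy()]
#' @return logical, with attribute `reasons` listing failed thresholds
#' @export
passes_selection <- function(census, policy = filter_policy()) {
  reasons <- character(0)
  if (census$n_taxa < policy$min_taxa)
    reasons <- c(reasons, sprintf("taxa %d < %d", census$n_taxa, policy$min_taxa))
  if (length(census$majors) < policy$min_major_clades)
    reasons <- c(reasons, sprintf("major clades %d < %d",
                                  length(census$majors), policy$min_major_clades))
  n2 <- sum(lengths(census$minors_by_major) >= 2L)
  if (n2 < policy$min_majors_with_two_minors)
    reasons <- c(reasons, sprintf("majors with >=2 minors %d < %d",
                                  n2, policy$min_majors_with_two_minors))
  structure(length(reasons) == 0L, reasons = reasons)
}

#' Eukaryote-monophyly screen
#'
#' Keep a family iff it contains no non-eukaryote leaves, or the eukaryote
#' leaf set forms one side of a bipartition of the unrooted tree (i.e. the
#' eukaryotes are monophyletic under some rooting). Rooting-invariant by
#' construction.
#' @param tree phylo (rooted or unrooted) whose leaves may include outgroup
#'   (non-eukaryote) taxa
#' @param eukaryotes character vector of eukaryote taxon ids
#' @return logical: keep (TRUE) or discard (FALSE)
#' @export
eukaryote_monophyly_filter <- function(tree, eukaryotes) {
  taxa <- leaf_taxon(tree$tip.label)
  is_euk <- taxa %in% eukaryotes
  if (!any(is_euk)) stop("family contains no eukaryote leaves")
  if (all(is_euk)) return(TRUE)
  euk_leaves <- sort(tree$tip.label[is_euk])
  if (length(euk_leaves) == 1L || sum(!is_euk) == 1L) return(TRUE)
  splits <- unrooted_splits(tree, trivial = FALSE)
  key <- paste(euk_leaves, collapse = ",")
  other <- paste(sort(tree$tip.label[!is_euk]), collapse = ",")
  key %in% splits || other %in% splits
}

#' Subset families by a census predicate
#'
#' @param families named list of phylo objects (or of `family_census`)
#' @param predicate function of a census returning TRUE/FALSE
#' @param tab a [taxon_table()]
#' @return the surviving sublist (same order as input)
#' @export
subset_families <- function(families, predicate, tab) {
  keep <- vapply(families, function(f) {
    cen <- if (inherits(f, "family_census")) f else family_census(f, tab)
    isTRUE(predicate(cen))
  }, logical(1))
  families[keep]
}

#' Read a presence/absence (copy-count) matrix
#'
#' TSV with families in rows (first column `family_id`) and taxa in columns;
#' integer copy counts.
#' @param path TSV path
#' @return integer matrix with family rownames
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "family_id") stop("first column must be family_id")
  m <- as.matrix(df[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$family_id
  m
}

#' Apply the selection policy to a family collection and report
#'
#' @param families named list of phylo objects, or a copy-count matrix
#'   (families x taxa)
#' @param tab a [taxon_table()]
#' @param policy a [filter_policy()]
#' @return data.frame: `family_id`, `n_taxa`, `n_major_clades`,
#'   `n_majors_with_two_minors`, `pass`, `reasons`
#' @export
selection_report <- function(families, tab, policy = filter_policy()) {
  censuses <- if (is.matrix(families))
    lapply(rownames(families), function(f)
      family_census(families[f, ], tab, family_id = f))
  else
    lapply(names(families), function(f)
      family_census(families[[f]], tab, family_id = f))
  rows <- lapply(censuses, function(cen) {
    ok <- passes_selection(cen, policy)
    data.frame(family_id = cen$family_id, n_taxa = cen$n_taxa,
               n_major_clades = length(cen$majors),
               n_majors_with_two_minors = sum(lengths(cen$minors_by_major) >= 2L),
               pass = as.logical(ok),
               reasons = paste(attr(ok, "reasons"), collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
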