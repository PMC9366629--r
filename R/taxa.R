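# Taxon tables: taxon -> (major clade, minor clade, data source). These drive
# the gene-family filters, the backbone constraints and the labelling of the
# earliest-branching group at the inferred root.

#' Default registry of major eukaryotic clades
#'
#' The recognised top-level groups; `Orphan` collects taxa of uncertain
#' placement. Override via the `registry` argument of [taxon_table()].
#' @export
default_major_clades <- function() {
  c("Opisthokonta", "Amoebozoa", "Archaeplastida", "Excavata", "SAR", "Orphan")
}

#' Construct and validate a taxon table
#'
#' @param df data.frame with columns `taxon_id`, `major_clade`, `minor_clade`,
#'   `source` (`genome`, `transcriptome` or `unknown`)
#' @param registry allowed major-clade names
#' @return a `taxon_table` (validated data.frame)
#' @export
taxon_table <- function(df, registry = default_major_clades()) {
  need <- c("taxon_id", "major_clade", "minor_clade", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("taxon table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (j in need) df[[j]] <- as.character(df[[j]])
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  if (any(grepl("[|[:space:]]", df$taxon_id)))
    stop("taxon_id must not contain whitespace or '|'")
  bad <- setdiff(unique(df$major_clade), registry)
  if (length(bad))
    stop("major_clade not in registry: ", paste(bad, collapse = ", "))
  bad_src <- setdiff(unique(df$source), c("genome", "transcriptome", "unknown"))
  if (length(bad_src))
    stop("source must be genome/transcriptome/unknown, got: ",
         paste(bad_src, collapse = ", "))
  attr(df, "registry") <- registry
  class(df) <- c("taxon_table", "data.frame")
  df
}

#' Read a taxon table from TSV
#'
#' Expects a header line `taxon_id  major_clade  minor_clade  source`.
#' @param path TSV path
#' @param registry allowed major-clade names
#' @return a `taxon_table`
#' @export
read_taxon_table <- function(path, registry = default_major_clades()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  taxon_table(df, registry = registry)
}

#' Write a taxon table to TSV
#' @param tab a `taxon_table`
#' @param path output path
#' @export
write_taxon_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[c("taxon_id", "major_clade",
                                          "minor_clade", "source")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tt_lookup <- function(tab, taxa, what) {
  i <- match(taxa, tab$taxon_id)
  if (anyNA(i))
    stop("taxa absent from taxon table: ", paste(taxa[is.na(i)], collapse = ", "))
  tab[[what]][i]
}

#' Taxa belonging to a clade label
#'
#' `clade` is matched against major clades first, then minor clades.
#' @param tab a `taxon_table`
#' @param clade clade name
#' @return character vector of taxon ids
#' @export
clade_taxa <- function(tab, clade) {
  hit <- tab$taxon_id[tab$major_clade == clade]
  if (!length(hit)) hit <- tab$taxon_id[tab$minor_clade == clade]
  if (!length(hit)) stop("unknown clade: ", clade)
  hit
}

#' Minimal clade label covering a taxon set
#'
#' Used to name the earliest-branching group at an inferred root: a single
#' taxon is named by itself, a set within one minor clade by that minor clade,
#' within one major clade by that major clade, otherwise `"mixed"`.
#' @param tab a `taxon_table`
#' @param taxa character vector of taxon ids
#' @return a single label
#' @export
covering_clade_label <- function(tab, taxa) {
  if (length(taxa) == 1L) return(taxa)
  minors <- unique(tt_lookup(tab, taxa, "minor_clade"))
  if (length(minors) == 1L) return(minors)
  majors <- unique(tt_lookup(tab, taxa, "major_clade"))
  if (length(majors) == 1L) return(majors)
  "mixed"
}
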