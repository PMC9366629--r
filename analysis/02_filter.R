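#!/usr/bin/env Rscript
# Stage 2: gene-family selection filters.
#
# Demonstrates the selection rules (minimum taxa, major-clade representation,
# minor-clade depth) on a constructed presence/absence panel, and the
# eukaryote-monophyly screen on small mixed trees. Writes
# results/filter/selection_report.tsv and monophyly_report.tsv.
suppressPackageStartupMessages(library(gtproot))

dir.create("results/filter", recursive = TRUE, showWarnings = FALSE)

taxa <- c(sprintf("met%02d", 1:12), sprintf("fun%02d", 1:12),
          sprintf("amo%02d", 1:4))
tab <- taxon_table(data.frame(
  taxon_id = taxa,
  major_clade = c(rep("Opisthokonta", 24), rep("Amoebozoa", 4)),
  minor_clade = c(rep("Metazoa", 12), rep("Fungi", 12), rep("Tubulinea", 4)),
  source = "transcriptome", stringsAsFactors = FALSE))
n_met <- c(11, 10, 12, 10, 11, 12, 9, 8, 10, 3, 0, 12)
n_fun <- c(10, 12, 11, 0, 0, 0, 10, 12, 9, 2, 12, 3)
n_amo <- c(2, 1, 0, 3, 2, 1, 0, 2, 1, 4, 2, 0)
counts <- matrix(0L, nrow = 12, ncol = length(taxa),
                 dimnames = list(sprintf("fam%02d", 1:12), taxa))
for (i in 1:12) {
  if (n_met[i] > 0) counts[i, sprintf("met%02d", seq_len(n_met[i]))] <- 1L
  if (n_fun[i] > 0) counts[i, sprintf("fun%02d", seq_len(n_fun[i]))] <- 1L
  if (n_amo[i] > 0) counts[i, sprintf("amo%02d", seq_len(n_amo[i]))] <- 1L
}

# thresholds scaled to the toy panel (2 majors available)
pol <- filter_policy(min_taxa = 12, min_major_clades = 2,
                     min_majors_with_two_minors = 1)
rep <- selection_report(counts, tab, pol)
utils::write.table(rep, "results/filter/selection_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sum(rep$pass), "of", nrow(rep), "families pass the selection policy\n")

censuses <- lapply(rownames(counts), function(f)
  family_census(counts[f, ], tab, family_id = f))
names(censuses) <- rownames(counts)
both <- subset_families(censuses, function(cen)
  clade_presence_count(cen, "Metazoa", tab) >= 10 &&
  clade_presence_count(cen, "Fungi", tab) >= 10, tab)
nofun <- subset_families(censuses, function(cen)
  clade_presence_count(cen, "Metazoa", tab) >= 10 &&
  clade_presence_count(cen, "Fungi", tab) == 0, tab)
cat("families with >=10 Metazoa and >=10 Fungi:", length(both),
    "(", paste(names(both), collapse = ", "), ")\n")
cat("families with >=10 Metazoa and no Fungi: ", length(nofun),
    "(", paste(names(nofun), collapse = ", "), ")\n")

# eukaryote-monophyly screen on mixed eukaryote/prokaryote pilot trees
pilots <- list(clean   = read_newick("((E1,E2),(B1,B2));"),
               mixed   = read_newick("((E1,B1),(E2,B2));"),
               eukonly = read_newick("(E1,E2,E3);", rooted = FALSE,
                                     binary = FALSE))
keep <- vapply(pilots, eukaryote_monophyly_filter,
               eukaryotes = c("E1", "E2", "E3"), logical(1))
mono <- data.frame(family = names(pilots), keep = keep)
utils::write.table(mono, "results/filter/monophyly_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("monophyly screen keeps:", paste(names(pilots)[keep], collapse = ", "),
    "| discards:", paste(names(pilots)[!keep], collapse = ", "), "\n")
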