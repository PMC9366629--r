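#!/usr/bin/env Rscript
# Stage 1: simulate the study datasets.
#
# Two datasets are written under results/data/:
#   * planted/ -- 10 taxa in a small eukaryote-like taxonomy (Opisthokonta
#     with Fungi + Metazoa, Amoebozoa, Excavata with Discoba + Metamonada,
#     one orphan lineage), true root planted between Fungi and everything
#     else; 60 multi-copy gene families under the duplication-loss process.
#   * random8/ -- a uniformly drawn 8-taxon tree with 100 families, used by
#     the unconstrained search stage.
suppressPackageStartupMessages(library(gtproot))

seed <- 2024L
out <- "results/data"

tab <- taxon_table(data.frame(
  taxon_id = c("fun1", "fun2", "met1", "met2", "amo1", "amo2",
               "dis1", "dis2", "mem1", "anc1"),
  major_clade = c(rep("Opisthokonta", 4), rep("Amoebozoa", 2),
                  rep("Excavata", 3), "Orphan"),
  minor_clade = c("Fungi", "Fungi", "Metazoa", "Metazoa",
                  "Tubulinea", "Tubulinea",
                  "Discoba", "Discoba", "Metamonada", "Ancyromonadida"),
  source = "genome", stringsAsFactors = FALSE))
truth <- read_newick(paste0("((fun1,fun2),(((met1,met2),(amo1,amo2)),",
                            "((dis1,dis2),(mem1,anc1))));"))

cat("== planted fungal-root dataset ==\n")
ds1 <- run_simulate(sim_params(10, dup_rate = 0.2, loss_rate = 0.2,
                               n_families = 60, seed = seed),
                    file.path(out, "planted"),
                    species_tree = truth, taxon_table = tab)
cat("true tree:", write_newick(ds1$species_tree), "\n\n")

cat("== random 8-taxon dataset ==\n")
ds2 <- run_simulate(sim_params(8, dup_rate = 0.2, loss_rate = 0.2,
                               n_families = 100, seed = seed + 1L),
                    file.path(out, "random8"))
cat("true tree:", write_newick(ds2$species_tree), "\n")
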