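#!/usr/bin/env Rscript
# Stage 3: reconciliation scoring of the planted dataset against its true
# tree, in both loss-counting modes. The gap between the full and pruned
# totals is the cost mass contributed by taxa absent from each family --
# exactly the quantity a reconciler cannot tell apart from true loss.
# Writes results/score/{full,pruned}/.
suppressPackageStartupMessages(library(gtproot))

seed <- 2024L
gt <- "results/data/planted/gene_trees.nwk"
if (!file.exists(gt)) stop("run analysis/01_simulate.R first")
trees <- read_gene_trees(gt)
params <- jsonlite::read_json("results/data/planted/params.json")
truth <- read_newick(params$species_tree)

full <- run_score(trees, truth, "results/score/full",
                  loss_mode = "full", seed = seed)
pruned <- run_score(trees, truth, "results/score/pruned",
                    loss_mode = "pruned", seed = seed)
cat(sprintf("total DL cost vs true tree (full-tree losses):  %g\n",
            full$total))
cat(sprintf("total DL cost vs true tree (pruned-tree losses): %g\n",
            pruned$total))
cat(sprintf("cost attributable to absent taxa: %g (%.1f%% of full)\n",
            full$total - pruned$total,
            100 * (full$total - pruned$total) / full$total))
cat(sprintf("families at zero cost: %d of %d\n",
            sum(full$families$cost == 0), nrow(full$families)))
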