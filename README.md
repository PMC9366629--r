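# gtproot

Rooting species trees by gene tree parsimony under a duplication–loss
criterion — with the machinery to study when that rooting can be trusted.

## The problem

Most gene trees are estimated unrooted, and a species tree assembled from
them inherits that ambiguity. Gene tree parsimony (GTP) roots the species
tree using multi-copy gene families: given a set of unrooted gene trees, it
seeks the rooted species tree *S* minimising the total reconciliation cost

```
C(S) = Σ_g min_over_rootings ( w_dup · dup(g, S) + w_loss · loss(g, S) )
```

where each gene tree *g* is embedded into *S* by the LCA mapping
(every gene node maps to the last common ancestor of the taxa below it), a
gene node is a **duplication** when its mapping equals a child's mapping,
and **losses** are counted from the path stretch between the mappings of a
parent and its child (d − 1 on speciation edges, d on duplication edges,
nothing above the gene root's mapping). Duplications and losses are
asymmetric in time, so — unlike a likelihood on unrooted topologies — the
optimal total cost differs between rootings of the same unrooted species
topology. That asymmetry is the rooting signal.

It is also the rooting hazard: a reconciler cannot distinguish a genuinely
lost gene from a gene missing because a taxon is under-sampled. Under
full-tree loss counting, taxa absent from a family register as losses, and
the cheapest way to explain a systematically under-sampled (or
genome-reduced) clade is to place it next to the root. `gtproot` implements
both the inference and a simulator designed to expose this confound.

## What the package provides

* **Reconciliation** (`dl_events_and_losses`, `dl_cost_unrooted`,
  `total_cost`): LCA mapping, event labels, loss counts, optimal rooting of
  unrooted gene trees; a readable R reference path plus a batched C++ engine,
  cross-checked against each other and against an exhaustive enumeration
  over all valid mappings (`exhaustive_reconciliation_oracle`). Two loss
  modes: `"full"` (absent taxa count as losses) and `"pruned"` (species tree
  restricted to each family's taxa first).
* **Search** (`run_replicates`, `hill_climb`, `exhaustive_species_search`):
  best-improvement rooted-SPR/NNI climbs from greedy stepwise-addition
  random starts, the replicated protocol with shuffled gene and leaf orders,
  and an exhaustive oracle for ≤ 7 taxa.
* **Root hypotheses** (`build_backbone`, `evaluate_hypotheses`,
  `compare_hypotheses`): named root splits (e.g. `fungi_others`,
  `opisthokonta_others`, `unikonta_bikonta`) as backbone constraints,
  constrained optima per replicate, Shapiro–Wilk screen and Wilcoxon
  rank-sum comparison against a reference hypothesis.
* **Gene-family filters** (`family_census`, `passes_selection`,
  `eukaryote_monophyly_filter`, `subset_families`): taxon- and clade-
  representation thresholds and the eukaryote-monophyly (lateral-transfer)
  screen, as pure functions of a family census.
* **Simulator** (`simulate_dataset`, `sim_params`): gene families evolved on
  a known rooted species tree under per-branch Poisson duplications and
  hazard-style losses, leaf-level retention (clade-biased missing data,
  logged separately from true loss), optional NNI noise, full truth logs
  replayable into the emitted trees.
* **Workflow** (`analysis/01_simulate.R` … `analysis/06_missing_data.R`):
  numbered drivers running the whole study — simulate, filter, score,
  search, hypotheses, missing-data artifact — writing TSV/JSON under
  `results/`.

## A worked example

```r
library(gtproot)

S <- read_newick("(((A,B),C),D);")              # rooted species tree
g <- read_newick("((A|1,C|1),(B|1,D|1));",      # unrooted gene family,
                 rooted = FALSE)                # leaves are taxon|copy
rec <- dl_cost_unrooted(g, S)
rec
#> DL reconciliation
#>   duplications:1 losses:3 cost:4 (loss_mode=full)
rec$root_split
#> [1] "D|1"
```

The AC|BD family conflicts with every rooting of the species tree; the
cheapest explanation places the gene root on the pendant edge of D and pays
1 duplication + 3 losses = 4. A congruent single-copy family costs 0, so

```r
f1 <- read_newick("((A|1,B|1),(C|1,D|1));", rooted = FALSE)
total_cost(list(f1 = f1, f2 = g), S)$total
#> [1] 4
```

On simulated data the full pipeline recovers a planted root:

```r
ds  <- simulate_dataset(sim_params(8, dup_rate = 0.2, loss_rate = 0.2,
                                   n_families = 100, seed = 5),
                        species_tree = simulate_species_tree(8, seed = 11))
res <- run_replicates(ds$gene_trees, search_config(n_replicates = 10, seed = 7))
res$summary$frequency[1]
#> [1] 10        # all 10 replicates find the same best tree
canonical_newick(res$best_tree) == canonical_newick(ds$species_tree)
#> [1] TRUE      # ... and it is the true rooted tree
```

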