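---
title: "Rooting species trees by duplication-loss gene tree parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting species trees by duplication-loss gene tree parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtproot)
```

## The model

A gene family evolves inside a species phylogeny by speciation, gene
duplication and gene loss. Given a rooted binary species tree $S$ and a
rooted binary gene tree $G$ whose leaves carry species labels (one gene copy
per leaf, written `taxon|copy`), the *LCA mapping* sends every gene node $g$
to the most recent common ancestor in $S$ of the species below $g$. Events
are then read off the mapping:

* $g$ is a **duplication** iff $M(g) = M(c)$ for at least one child $c$;
  otherwise $g$ is a **speciation**;
* the edge from $g$ down to child $c$ implies $d - 1$ **losses** if $g$ is a
  speciation and $d$ if a duplication, where $d$ is the number of species-tree
  edges between $M(g)$ and $M(c)$;
* no losses are charged above $M(\text{root of } G)$.

The reconciliation cost is $w_{dup}\,D + w_{loss}\,L$ with unit weights by
default. The LCA mapping minimises this cost over all valid mappings — the
package carries an exhaustive enumeration over mappings
(`exhaustive_reconciliation_oracle`) purely to test that claim on random
instances, and the test suite checks it on hundreds of them.

Gene trees usually arrive **unrooted**. `dl_cost_unrooted()` scores a root
placed on each of the $2n-3$ edges and keeps the minimum; ties are broken by
a fixed lexicographic order on the edges' leaf bipartitions so results are
reproducible without hidden state. The total over a family collection
(`total_cost()`) is what the species-tree search minimises. Because
duplication and loss are directional, this total distinguishes rootings of
the same unrooted species topology — that is the entire source of rooting
information, and the package's central subject.

### Counting losses for absent taxa

Two conventions are implemented, and the choice matters more than any other
parameter:

* `loss_mode = "full"` (default): losses are counted on the complete species
  tree, so a taxon absent from a family is explained as one or more losses.
  This is the behaviour of classic GTP software, and it conflates genuine
  loss with missing data.
* `loss_mode = "pruned"`: the species tree is first restricted to the
  family's taxon set (suppressing degree-2 nodes), so absence is free.

The two modes are linked by an identity the tests exploit: the pruned-mode
cost on $S$ equals the full-mode cost on $S$ pruned to the family's taxa.

## Search

`run_replicates()` implements a replicated randomised search:

* a greedy starting tree per replicate (`random_start_tree()`): taxa are
  inserted in seeded random order at the attachment point minimising the
  cost over a subsample of families (default 20);
* best-improvement hill climbing under rooted SPR (default; includes
  regrafts onto the root edge, i.e. root relocation) or rooted NNI, with a
  seeded random tie-break among equal best neighbours; the accepted-cost
  sequence is strictly decreasing, so termination is guaranteed;
* per replicate, the gene order and every gene tree's leaf order are
  shuffled and logged. The scorer here is order-invariant by construction,
  so these shuffles cannot change any cost; they are retained because the
  replication protocol they belong to is part of the method being studied,
  and because they document that our results cannot depend on input order.
* replicate-to-replicate variation therefore comes only from the seeded
  starts and tie-breaks; the summary ranks distinct best topologies by cost
  and frequency, and labels each replicate's earliest-branching group (the
  smaller root child, named by the minimal covering clade from the taxon
  table).

`exhaustive_species_search()` scores every rooted topology (via
`phangorn::allTrees`) up to 7 taxa (10,395 trees) and is the oracle against
which the heuristic is validated: on twenty 5–6-taxon simulated datasets with
10 restarts the climb reaches the global optimum in at least 19 (observed:
all 20).

## Root hypotheses and statistics

A root hypothesis is a backbone: a named taxon group forced to be one child
of the root, everything else the other, relationships within each side free.
Built-ins mirror the classical candidates (`fungi_others`,
`opisthokonta_others`, `discoba_others`, `unikonta_bikonta`,
`ancyromonadida_metamonada_others`). The Unikonta composition is an argument
(`unikonta = c("Opisthokonta", "Amoebozoa")` by default), not hard-coded
biology, because its definition varies across the literature. Backbones may
also be arbitrary user-supplied group partitions with a topology over
groups.

`evaluate_hypotheses()` runs a constrained climb per replicate and
hypothesis (constraint-consistent random starts; neighbourhoods filtered to
constraint-consistent trees), yielding a replicate × hypothesis cost table.
Since constrained optima can only be worse than unconstrained ones, and cost
distributions across replicates are typically non-normal, the comparison is
rank-based: a Shapiro–Wilk screen per hypothesis motivates Wilcoxon
rank-sum tests of each hypothesis against the reference at $\alpha = 0.05$,
uncorrected by default (Holm available via `holm = TRUE`). Both tests wrap
the standard implementations in `stats`; the exact small-sample rank-sum p
is verified in the tests against a direct enumeration of rank assignments.

## The simulator

`simulate_dataset()` draws gene families on a known rooted species tree:

* **species tree**: uniform over rooted binary topologies (sequential
  insertion at a uniformly chosen edge), or user-supplied;
* **duplication**: along each species branch, each incoming gene lineage
  acquires $k \sim \text{Poisson}(\lambda_{dup})$ duplications, realised as
  sequential random splits among its copies;
* **loss**: each resulting copy survives the branch with probability
  $e^{-\lambda_{loss}}$ (hazard-style rather than explicit Poisson loss
  events — chosen because it gives a closed-form copy-number expectation);
* **retention**: at a species leaf each surviving copy is *observed* with
  probability `retention[taxon]`. Retention misses are logged as
  `unsampled`, distinct from `loss` in the truth log but — by design —
  indistinguishable to the reconciler. This is the missing-data/loss
  confound in its purest form;
* **noise**: optional random NNIs on the realised unrooted tree emulate
  gene-tree estimation error;
* families observed with fewer than 3 leaves are discarded and redrawn
  under a derived seed, with redraw counts reported.

Every event carries its species branch and lineage id, so `replay_truth()`
can rebuild each emitted topology from the log alone; the tests assert this
replay on every simulated family. The mean observed copy number per taxon
has the closed form
$\text{retention} \cdot \big((1+\lambda_{dup})\,e^{-\lambda_{loss}}\big)^{\text{depth}}$,
checked against 10,000 raw draws within three standard errors.

What the simulator does *not* emulate: sequence evolution and tree
estimation (noise is topological only), transfers, rate variation across
families or branches, and correlated loss. A clean pass on these synthetic
data therefore shows that the inference machinery is correct and that the
studied artifacts arise from the model itself — not that real data are free
of other failure modes.

## Study conditions and design choices

The bundled experiments (`experiment_*`, driven by `analysis/` and the
acceptance script) fix their conditions once:

* oracle checks: 200 random instances with ≤ 5 species and ≤ 8 gene leaves
  (the exhaustive mapping enumeration is exponential; these sizes keep it
  exact and fast), and 100 random unrooted pairs at ≤ 6 species;
* search validation: twenty datasets of 5–6 taxa × 20 families at
  $\lambda_{dup} = \lambda_{loss} = 0.1$, 10 restarts, versus the exhaustive
  oracle;
* root recovery: 8 taxa × 100 families at rates 0.2, complete sampling, 10
  replicates — sizes at which a desk machine completes in seconds per
  replicate while the rooting signal (a few hundred events per dataset) is
  realistic for a medium phylogenomic panel;
* missing-data artifact: a 9-taxon, three-clade tree rooted on clade one;
  retention 0.4 on the *non-basal* third clade versus complete sampling,
  20 replicates per arm. The measured quantity is the fraction of
  replicates whose earliest-branching group lies inside the reduced clade;
* hypothesis discrimination: a 10-taxon toy eukaryote taxonomy with the
  true root between Fungi and everything else, 60 families at rates 0.2,
  the five built-in hypotheses at 20 replicates each, Wilcoxon against the
  fungal root.

Numerical and procedural choices worth recording: unit cost weights
(configurable); rooting and neighbour ties broken deterministically
(lexicographic canonical forms) with seeded randomness only where the
protocol wants replicate variation; all seeds derived from one global seed
through a fixed string hash, so a single integer reproduces a whole run
byte-for-byte; species trees are required to be strictly binary while gene
trees may arrive with polytomies, which are randomly resolved under a
recorded seed (duplication-loss counting is defined on binary trees);
branch lengths and support values are parsed and discarded throughout — the
method is topology-only.

## Limitations

The search is a local climb with restarts: on adversarial cost surfaces it
can stall in local optima (the oracle comparison bounds how often this
happens at small sizes, not at large ones). Loss counting in `"full"` mode
is the faithful-but-confounded convention; conclusions about deep roots
drawn under it should always be re-examined under `"pruned"` mode and under
retention-biased simulations of the kind bundled here. The statistics treat
replicates as independent draws from the search's stationary behaviour;
they quantify search/tree-space uncertainty, not phylogenetic error.
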