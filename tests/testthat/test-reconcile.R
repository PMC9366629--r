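# Duplication-loss reconciliation: worked examples, the exhaustive-mapping
# oracle, the explicit-rooting oracle, and the structural invariants.

S3 <- read_newick("((A,B),C);")
S4 <- read_newick("(((A,B),C),D);")

test_that("lca_map follows the LCA construction", {
  g <- read_newick("((A|1,B|1),C|1);")
  m <- lca_map(g, S3)
  ab_gene <- lca_node(g, c("A|1", "B|1"))
  expect_identical(m[ab_gene], lca_node(S3, c("A", "B")))
  expect_identical(m[ape::Ntip(g) + 1L], ape::Ntip(S3) + 1L)  # root -> root
  g2 <- read_newick("(A|1,(A|2,B|1));")
  m2 <- lca_map(g2, S3)
  ab_sp <- lca_node(S3, c("A", "B"))
  expect_identical(m2[lca_node(g2, c("A|2", "B|1"))], ab_sp)
  expect_identical(m2[ape::Ntip(g2) + 1L], ab_sp)   # root maps below species root
  expect_identical(m2[which(g2$tip.label == "A|1")],
                   which(S3$tip.label == "A"))      # leaf identity
  expect_error(lca_map(read_newick("((A|1,Z|1),C|1);"), S3), "absent")
})

test_that("event labelling and loss counting match the worked examples", {
  r0 <- dl_events_and_losses(read_newick("((A|1,B|1),C|1);"), S3)
  expect_identical(c(r0$dup_count, r0$loss_count), c(0L, 0L))
  expect_identical(r0$cost, 0)

  r1 <- dl_events_and_losses(read_newick("(A|1,(A|2,B|1));"), S3)
  expect_identical(c(r1$dup_count, r1$loss_count), c(1L, 1L))
  expect_identical(r1$cost, 2)
  expect_identical(unname(r1$events[4]), "duplication")  # gene root duplicates

  # missing taxon charged as a loss in full mode, not in pruned mode
  g_ac <- read_newick("(A|1,C|1);")
  r_full <- dl_events_and_losses(g_ac, S3, loss_mode = "full")
  expect_identical(c(r_full$dup_count, r_full$loss_count), c(0L, 1L))
  r_pruned <- dl_events_and_losses(g_ac, S3, loss_mode = "pruned")
  expect_identical(c(r_pruned$dup_count, r_pruned$loss_count), c(0L, 0L))

  # weights scale the cost
  r_w <- dl_events_and_losses(read_newick("(A|1,(A|2,B|1));"), S3,
                              weights = cost_weights(dup = 2, loss = 0.5))
  expect_identical(r_w$cost, 2.5)
  expect_error(cost_weights(-1, 1), "non-negative")
  expect_error(cost_weights(0, 0), "zero")
})

test_that("unrooted scoring finds the optimal rooting of the ac|bd family", {
  gu <- read_newick("((A|1,C|1),(B|1,D|1));", rooted = FALSE)
  rec <- dl_cost_unrooted(gu, S4)
  expect_identical(rec$cost, 4)
  expect_identical(c(rec$dup_count, rec$loss_count), c(1L, 3L))
  expect_identical(rec$root_split, "D|1")  # the d-pendant edge

  # brute force over all 5 rootings agrees and confirms the minimum
  all_costs <- vapply(seq_len(nrow(gu$edge)), function(e)
    dl_events_and_losses(root_on_edge(gu, e), S4)$cost, numeric(1))
  expect_identical(min(all_costs), 4)
  expect_true(all(rec$cost <= all_costs))

  # 3-leaf unrooted tree compatible with the species tree costs nothing
  g3 <- read_newick("(A|1,B|1,C|1);", rooted = FALSE, binary = FALSE)
  expect_identical(dl_cost_unrooted(g3, S3)$cost, 0)
})

test_that("unrooted minimisation equals the explicit per-edge minimum", {
  for (seed in 1:100) {
    inst <- rand_unrooted_instance(seed)
    if (ape::Ntip(inst$gene) < 3) next
    rec <- dl_cost_unrooted(inst$gene, inst$sp)
    explicit <- min(vapply(seq_len(nrow(inst$gene$edge)), function(e)
      dl_events_and_losses(root_on_edge(inst$gene, e), inst$sp)$cost,
      numeric(1)))
    expect_identical(rec$cost, explicit)
    # batched engine agrees too
    cpp <- total_cost(list(g = inst$gene), inst$sp)
    expect_identical(cpp$total, explicit)
  }
})

test_that("LCA-based cost equals the exhaustive mapping oracle", {
  for (seed in 1:200) {
    inst <- rand_instance(seed)
    lca_cost <- dl_events_and_losses(inst$gene, inst$sp)$cost
    expect_identical(lca_cost,
                     exhaustive_reconciliation_oracle(inst$gene, inst$sp),
                     info = paste("seed", seed))
  }
  expect_error(
    exhaustive_reconciliation_oracle(ape::rtree(9, br = NULL), S3),
    "too large")
})

test_that("reference and batched engines agree on whole datasets", {
  sp <- simulate_species_tree(6, seed = 3)
  ds <- simulate_dataset(sim_params(6, 0.4, 0.3, 25, seed = 17),
                         species_tree = sp)
  for (lm in c("full", "pruned")) {
    a <- total_cost(ds$gene_trees, sp, loss_mode = lm, engine = "cpp")
    b <- total_cost(ds$gene_trees, sp, loss_mode = lm, engine = "r")
    expect_identical(a$families$cost, b$families$cost)
    expect_identical(a$families$dup_count, b$families$dup_count)
    expect_identical(a$families$loss_count, b$families$loss_count)
  }
})

test_that("pruned mode equals full mode on the explicitly pruned species tree", {
  sp <- simulate_species_tree(7, seed = 8)
  ds <- simulate_dataset(sim_params(7, 0.2, 0.5, 20, seed = 21),
                         species_tree = sp)
  for (g in ds$gene_trees) {
    taxa <- unique(leaf_taxon(g$tip.label))
    if (length(taxa) < 2) next
    pruned_sp <- ape::keep.tip(sp, taxa)
    a <- total_cost(list(g = g), sp, loss_mode = "pruned")$total
    b <- total_cost(list(g = g), pruned_sp, loss_mode = "full")$total
    expect_identical(a, b)
  }
})

test_that("cost invariants hold on simulated families", {
  sp <- simulate_species_tree(6, seed = 5)
  ds <- simulate_dataset(sim_params(6, 0.5, 0.3, 40, seed = 11),
                         species_tree = sp)
  res <- total_cost(ds$gene_trees, sp)
  # non-negative integral counts
  expect_true(all(res$families$dup_count >= 0))
  expect_true(all(res$families$loss_count >= 0))
  # k copies of a taxon force at least k - 1 duplications
  for (i in seq_along(ds$gene_trees)) {
    kmax <- max(table(leaf_taxon(ds$gene_trees[[i]]$tip.label)))
    expect_gte(res$families$dup_count[i], kmax - 1)
  }
  # permuting family order leaves the total unchanged
  perm <- sample(length(ds$gene_trees))
  expect_identical(total_cost(ds$gene_trees[perm], sp)$total, res$total)
  # empty collection rejected
  expect_error(total_cost(list(), sp), "empty")
})

test_that("congruent single-copy families cost zero under any weights", {
  sp <- simulate_species_tree(8, seed = 13)
  g <- sp
  g$tip.label <- paste0(sp$tip.label, "|1")
  for (w in list(cost_weights(), cost_weights(3, 1), cost_weights(1, 7)))
    expect_identical(dl_events_and_losses(g, sp, weights = w)$cost, 0)
  gu <- ape::unroot(g)
  expect_identical(dl_cost_unrooted(gu, sp)$cost, 0)
})

test_that("LCA cost never exceeds the cost of the true event history", {
  # parsimony bound: reconciliation against the generating tree costs at most
  # the number of true events (duplications + losses + unsampled copies)
  sp <- simulate_species_tree(6, seed = 19)
  ds <- simulate_dataset(sim_params(6, 0.3, 0.3, 60, seed = 23,
                                    retention = 0.8),
                         species_tree = sp)
  res <- total_cost(ds$gene_trees, sp)
  ev <- ds$truth$events
  for (i in seq_along(ds$gene_trees)) {
    id <- names(ds$gene_trees)[i]
    n_true <- sum(ev$family_id == id)   # every event has weight 1
    expect_lte(res$families$cost[i], n_true)
  }
})
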