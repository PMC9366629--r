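# Species-tree search: moves, starts, hill climbing, the exhaustive oracle
# and the replicate protocol.

test_that("rooted NNI on a 3-taxon tree yields the two alternatives", {
  nb <- tree_neighbors(read_newick("((A,B),C);"), "nni")
  expect_length(nb, 2L)
  keys <- sort(vapply(nb, canonical_newick, character(1)))
  expect_identical(keys, c("((A,C),B);", "(A,(B,C));"))
})

test_that("rooted SPR reaches trees with a different earliest brancher", {
  tr <- read_newick("(((A,B),C),D);")
  nb <- tree_neighbors(tr, "spr")
  ebs <- vapply(nb, function(t) {
    sides <- lapply(gtproot:::phylo_to_clist(t), gtproot:::clist_leaves)
    paste(sort(sides[[which.min(lengths(sides))]]), collapse = ",")
  }, character(1))
  expect_true(any(ebs != "D"))   # the root moved in at least one neighbour
  # every neighbour is rooted, binary, same taxa, and none equals the origin
  for (t in nb) {
    expect_true(ape::is.rooted(t) && ape::is.binary(t))
    expect_setequal(t$tip.label, tr$tip.label)
    expect_false(trees_isomorphic(t, tr))
  }
  expect_false(anyDuplicated(vapply(nb, canonical_newick, character(1))) > 0)
})

test_that("constrained neighbourhoods respect the backbone", {
  tab <- toy_tab()
  bb <- build_backbone("opisthokonta_others", tab)
  start <- random_start_tree(tab$taxon_id, list(), seed = 4, constraint = bb)
  expect_true(backbone_consistent(start, bb))
  nb <- tree_neighbors(start, "spr", constraint = bb)
  expect_gt(length(nb), 0L)
  for (t in nb) expect_true(backbone_consistent(t, bb))
})

test_that("random_start_tree is deterministic and exact on clean data", {
  sp <- simulate_species_tree(6, seed = 2)
  ds <- simulate_dataset(sim_params(6, 0, 0, 15, seed = 41),
                         species_tree = sp)
  s1 <- random_start_tree(sp$tip.label, ds$gene_trees, seed = 9)
  s2 <- random_start_tree(sp$tip.label, ds$gene_trees, seed = 9)
  expect_identical(write_newick(s1), write_newick(s2))
  # congruent noiseless families: the greedy tree already has cost zero
  expect_identical(total_cost(ds$gene_trees, s1)$total, 0)
})

test_that("hill climbing is monotone and stops at local optima", {
  sp <- simulate_species_tree(6, seed = 3)
  ds <- simulate_dataset(sim_params(6, 0.1, 0.1, 20, seed = 43),
                         species_tree = sp)
  prep <- prepare_families(ds$gene_trees)
  cfg <- search_config(seed = 11)
  ex <- exhaustive_species_search(ds$gene_trees)
  # starting at the global optimum returns it unchanged
  rec0 <- hill_climb(prep, ex$best_tree, cfg)
  expect_identical(rec0$best_cost, ex$best_cost)
  expect_identical(rec0$iterations, 0L)
  expect_true(trees_isomorphic(rec0$best_tree, ex$best_tree))
  # from a random start the accepted costs strictly decrease
  start <- random_start_tree(sp$tip.label, ds$gene_trees, seed = 5,
                             subsample = 3)
  rec <- hill_climb(prep, start, cfg)
  expect_true(all(diff(rec$trajectory) < 0))
  expect_lte(rec$best_cost, rec$start_cost)
  expect_true(ape::is.binary(rec$best_tree) && ape::is.rooted(rec$best_tree))
})

test_that("exhaustive search scores every rooted topology and reports ties", {
  # 15 rooted topologies at n = 4
  g <- list(gf1 = read_newick("((A|1,B|1),(C|1,D|1));", rooted = FALSE))
  ex <- exhaustive_species_search(g, taxa = c("A", "B", "C", "D"))
  expect_identical(ex$n_scored, 15L)
  # a single AB|CD quartet cannot choose the root side: ties expected
  expect_gt(length(ex$co_optima), 1L)
  expect_error(exhaustive_species_search(g, taxa = LETTERS[1:8]), "7 taxa")
  # perfect UNROOTED single-copy data carry no rooting signal: all rootings
  # of the true unrooted topology are co-optimal at cost zero
  sp <- simulate_species_tree(5, seed = 6)
  ds <- simulate_dataset(sim_params(5, 0, 0, 20, seed = 47),
                         species_tree = sp)
  ex2 <- exhaustive_species_search(ds$gene_trees)
  expect_identical(ex2$best_cost, 0)
  expect_length(ex2$co_optima, 2L * 5L - 3L)
  expect_true(any(vapply(ex2$co_optima, trees_isomorphic, logical(1),
                         t2 = sp)))
  # the same families as ROOTED trees identify the root uniquely
  rooted <- lapply(seq_len(10), function(i) {
    g <- sp
    g$tip.label <- paste0(sp$tip.label, "|1")
    g
  })
  names(rooted) <- sprintf("rf%02d", seq_along(rooted))
  ex3 <- exhaustive_species_search(rooted, taxa = sp$tip.label)
  expect_identical(ex3$best_cost, 0)
  expect_length(ex3$co_optima, 1L)
  expect_true(trees_isomorphic(ex3$best_tree, sp))
})

test_that("run_replicates produces records, summary and stable seeds", {
  sp <- simulate_species_tree(6, seed = 7)
  ds <- simulate_dataset(sim_params(6, 0.2, 0.2, 20, seed = 51),
                         species_tree = sp)
  cfg <- search_config(n_replicates = 3, seed = 13)
  res <- run_replicates(ds$gene_trees, cfg)
  expect_identical(nrow(res$records), 3L)
  expect_true(all(res$records$total_cost <= res$records$start_cost))
  expect_identical(sum(res$summary$frequency), 3L)
  expect_identical(min(res$summary$relative_cost), 1)
  # rerun reproduces identical records
  res2 <- run_replicates(ds$gene_trees, cfg)
  expect_identical(res$records, res2$records)
  # single replicate reduces to one hill climb result
  cfg1 <- search_config(n_replicates = 1, seed = 13)
  res1 <- run_replicates(ds$gene_trees, cfg1)
  expect_identical(nrow(res1$records), 1L)
})

test_that("gene order never changes a total cost", {
  sp <- simulate_species_tree(6, seed = 8)
  ds <- simulate_dataset(sim_params(6, 0.3, 0.2, 15, seed = 53),
                         species_tree = sp)
  t_any <- simulate_species_tree(6, seed = 99, labels = sp$tip.label)
  base <- total_cost(ds$gene_trees, t_any)$total
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(length(ds$gene_trees))
    expect_identical(total_cost(ds$gene_trees[perm], t_any)$total, base)
  }
})

test_that("earliest_branching_group summarises the smaller root side", {
  tab <- toy_tab()
  tr <- read_newick(paste0("((fun1,fun2),(((met1,met2),(amo1,amo2)),",
                           "((dis1,dis2),(mem1,anc1))));"))
  ebg <- earliest_branching_group(tr, tab)
  expect_identical(ebg$label, "Fungi")
  expect_setequal(ebg$taxa, c("fun1", "fun2"))
})
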