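# Simulator: distribution of species trees, the duplication-loss process,
# truth-log replay, noise, and dataset determinism.

test_that("simulate_species_tree draws uniform rooted topologies", {
  # support at n = 3
  tops3 <- vapply(1:30, function(s)
    canonical_newick(simulate_species_tree(3, seed = s)), character(1))
  expect_true(all(tops3 %in% c("((T01,T02),T03);", "((T01,T03),T02);",
                               "(T01,(T02,T03));")))
  # shape at n = 5: binary, 4 internal nodes
  t5 <- simulate_species_tree(5, seed = 1)
  expect_equal(t5$Nnode, 4L)
  expect_true(ape::is.binary(t5) && ape::is.rooted(t5))
  expect_error(simulate_species_tree(2, seed = 1), ">= 3")
  # uniformity over the 15 rooted topologies at n = 4:
  # each frequency ~ Bin(n, 1/15); allow 4 standard errors
  n <- 6000L
  tops <- vapply(1:n, function(s)
    canonical_newick(simulate_species_tree(4, seed = s)), character(1))
  freq <- table(tops)
  expect_length(freq, 15L)
  se <- sqrt((1 / 15) * (14 / 15) / n)
  expect_true(all(abs(freq / n - 1 / 15) < 4 * se))
})

test_that("degenerate rates reproduce the species tree exactly", {
  sp <- simulate_species_tree(6, seed = 4)
  ds <- simulate_dataset(sim_params(6, dup_rate = 0, loss_rate = 0,
                                    n_families = 5, seed = 31),
                         species_tree = sp)
  for (g in ds$gene_trees) {
    expect_identical(sort(leaf_taxon(g$tip.label)), sort(sp$tip.label))
    expect_true(trees_isomorphic(strip_copies(g), ape::unroot(sp),
                                 rooted = FALSE))
  }
  expect_identical(total_cost(ds$gene_trees, sp)$total, 0)
  expect_identical(nrow(ds$truth$events), 0L)
})

test_that("without duplications every family is single-copy", {
  sp <- simulate_species_tree(6, seed = 4)
  ds <- simulate_dataset(sim_params(6, dup_rate = 0, loss_rate = 0.4,
                                    n_families = 30, seed = 7),
                         species_tree = sp)
  expect_true(all(ds$truth$census <= 1))
  res <- total_cost(ds$gene_trees, sp)
  expect_true(all(res$families$dup_count == 0))
})

test_that("truth replay reproduces every emitted family", {
  sp <- simulate_species_tree(7, seed = 9)
  ds <- simulate_dataset(sim_params(7, 0.3, 0.3, 25, seed = 13,
                                    retention = 0.9),
                         species_tree = sp)
  for (id in names(ds$gene_trees)) {
    ev <- ds$truth$events[ds$truth$events$family_id == id, , drop = FALSE]
    rp <- replay_truth(ev, sp)
    expect_true(trees_isomorphic(ape::unroot(rp), ds$gene_trees[[id]],
                                 rooted = FALSE), info = id)
  }
})

test_that("mean observed copies match the branch-process expectation", {
  # E[copies at taxon] = retention * ((1 + dup) * exp(-loss))^depth
  sp <- read_newick("(((T01,T02),T03),(T04,T05));")
  dup <- 0.3; loss <- 0.2; ret <- 0.8
  nfam <- 10000L
  p <- sim_params(5, dup, loss, n_families = nfam, retention = ret, seed = 3)
  # census over raw draws (no redraw filtering, which truncates the
  # distribution): simulate families directly
  counts <- matrix(0L, nrow = 5, ncol = nfam,
                   dimnames = list(sp$tip.label, NULL))
  for (i in seq_len(nfam)) {
    f <- gtproot:::simulate_gene_family_raw(sp, p, 1000L + i)
    counts[names(f), i] <- f
  }
  depth <- vapply(sp$tip.label, function(tx)
    node_depth_distance(sp, ape::Ntip(sp) + 1L, which(sp$tip.label == tx)),
    integer(1))
  expected <- ret * ((1 + dup) * exp(-loss))^depth
  for (tx in sp$tip.label) {
    m <- mean(counts[tx, ])
    se <- stats::sd(counts[tx, ]) / sqrt(nfam)
    expect_lt(abs(m - expected[[tx]]), 3 * se + 1e-9)
  }
})

test_that("apply_noise is identity at zero and a quartet NNI otherwise", {
  g4 <- read_newick("((A|1,B|1),(C|1,D|1));", rooted = FALSE)
  expect_identical(apply_noise(g4, 0L, seed = 1), g4)
  n1 <- apply_noise(g4, 1L, seed = 1)
  # one NNI on a quartet yields one of the two other topologies
  expect_false(trees_isomorphic(n1, g4, rooted = FALSE))
  others <- c("((A|1,C|1),(B|1,D|1));", "((A|1,D|1),(B|1,C|1));")
  expect_true(any(vapply(others, function(s)
    trees_isomorphic(n1, read_newick(s, rooted = FALSE), rooted = FALSE),
    logical(1))))
  g3 <- read_newick("(A|1,B|1,C|1);", rooted = FALSE, binary = FALSE)
  expect_warning(n3 <- apply_noise(g3, 2L, seed = 1), "no internal edge")
  expect_identical(n3, g3)
})

test_that("noise degrades fit to the true tree on average", {
  sp <- simulate_species_tree(8, seed = 15)
  base <- simulate_dataset(sim_params(8, 0.2, 0.2, 60, seed = 33),
                           species_tree = sp)
  cost0 <- total_cost(base$gene_trees, sp)$total
  # 3-leaf families warn (no internal edge) and pass through unchanged
  noisy2 <- lapply(seq_along(base$gene_trees), function(i)
    suppressWarnings(apply_noise(base$gene_trees[[i]], 2L, seed = 500 + i)))
  noisy5 <- lapply(seq_along(base$gene_trees), function(i)
    suppressWarnings(apply_noise(base$gene_trees[[i]], 5L, seed = 900 + i)))
  cost2 <- total_cost(noisy2, sp)$total
  cost5 <- total_cost(noisy5, sp)$total
  expect_gt(cost2, cost0)
  expect_gte(cost5, cost2 - 0.05 * cost2)  # trend, allowing noise wobble
})

test_that("datasets are deterministic and write byte-identical files", {
  p <- sim_params(5, 0.2, 0.2, 10, seed = 77)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(lapply(d1$gene_trees, write_newick),
                   lapply(d2$gene_trees, write_newick))
  out1 <- file.path(tempfile(), "a"); out2 <- file.path(tempfile(), "b")
  write_dataset(d1, out1); write_dataset(d2, out2)
  for (f in c("gene_trees.nwk", "taxa.tsv", "truth_events.tsv",
              "params.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  expect_length(readLines(file.path(out1, "gene_trees.nwk")), 10L)
})

test_that("families below three leaves are redrawn and counted", {
  sp <- simulate_species_tree(4, seed = 1)
  p <- sim_params(4, dup_rate = 0, loss_rate = 1.2, n_families = 30,
                  seed = 19)
  ds <- simulate_dataset(p, species_tree = sp)
  expect_true(all(vapply(ds$gene_trees, ape::Ntip, integer(1)) >= 3L))
  expect_gt(sum(ds$truth$redraws), 0L)
})

test_that("sim_params validates its inputs", {
  expect_error(sim_params(2, seed = 1), "n_taxa")
  expect_error(sim_params(5, dup_rate = -1, seed = 1), "dup_rate")
  expect_error(sim_params(5, retention = 1.3, seed = 1), "retention")
})
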