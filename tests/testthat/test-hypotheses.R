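# Root hypotheses as backbones, constrained evaluation, and the rank-based
# statistics.

test_that("built-in backbones resolve the named group against the rest", {
  tab <- toy_tab()
  bb <- build_backbone("opisthokonta_others", tab)
  expect_setequal(bb$groups[[1]], c("fun1", "fun2", "met1", "met2"))
  expect_setequal(bb$groups$others,
                  setdiff(tab$taxon_id, bb$groups[[1]]))
  bb2 <- build_backbone("ancyromonadida_metamonada_others", tab)
  expect_setequal(bb2$groups[[1]], c("anc1", "mem1"))
  bb3 <- build_backbone("unikonta_bikonta", tab)
  expect_setequal(bb3$groups[[1]],
                  c("fun1", "fun2", "met1", "met2", "amo1", "amo2"))
  expect_error(build_backbone("glaucophyta_others", tab), "unknown")
  # a clade absent from the table errors by name
  tab_noexc <- taxon_table(as.data.frame(tab)[tab$major_clade != "Excavata", ])
  expect_error(build_backbone("discoba_others", tab_noexc), "unknown clade")
  # overlapping custom groups rejected
  expect_error(build_backbone(list(hypothesis_id = "bad",
    groups = list(a = c("fun1", "fun2"), b = c("fun2", "met1"),
                  rest = setdiff(tab$taxon_id, c("fun1", "fun2", "met1")))),
    tab), "overlap")
})

test_that("backbone consistency is the root-split test", {
  tab <- toy_tab()
  bb <- build_backbone("fungi_others", tab)
  t_true <- read_newick(paste0("((fun1,fun2),(((met1,met2),(amo1,amo2)),",
                               "((dis1,dis2),(mem1,anc1))));"))
  t_wrong <- read_newick(paste0("(((fun1,fun2),((met1,met2),(amo1,amo2))),",
                                "((dis1,dis2),(mem1,anc1)));"))
  expect_true(backbone_consistent(t_true, bb))
  expect_false(backbone_consistent(t_wrong, bb))
})

test_that("constrained optima are never better than unconstrained ones", {
  ds <- planted_fungi_dataset(n_families = 25, seed = 61)
  tab <- ds$taxon_table
  cfg <- search_config(n_replicates = 2, seed = 17, restarts = 2)
  free <- run_replicates(ds$gene_trees, cfg, tab)
  for (h in c("fungi_others", "opisthokonta_others")) {
    cfg_h <- cfg
    cfg_h$constraint <- build_backbone(h, tab)
    con <- run_replicates(ds$gene_trees, cfg_h, tab)
    expect_gte(min(con$records$total_cost), min(free$records$total_cost))
    for (t in con$trees)
      expect_true(backbone_consistent(t, cfg_h$constraint))
  }
})

test_that("a backbone matching the optimum's root split is not binding", {
  ds <- planted_fungi_dataset(n_families = 30, seed = 63)
  tab <- ds$taxon_table
  cfg <- search_config(n_replicates = 2, seed = 19, restarts = 3)
  free <- run_replicates(ds$gene_trees, cfg, tab)
  best_split <- earliest_branching_group(free$best_tree, tab)$taxa
  bb <- build_backbone(list(hypothesis_id = "optimum_split",
                            groups = list(side = best_split,
                                          rest = setdiff(tab$taxon_id,
                                                         best_split))), tab)
  cfg_c <- cfg; cfg_c$constraint <- bb
  con <- run_replicates(ds$gene_trees, cfg_c, tab)
  expect_identical(min(con$records$total_cost),
                   min(free$records$total_cost))
})

test_that("wilcoxon_rank_sum matches exact enumeration and is symmetric", {
  # independent oracle: enumerate all C(6,3) rank assignments
  enum_p <- local({
    x <- c(1, 2, 3); y <- c(4, 5, 6)
    pooled <- c(x, y)
    combos <- utils::combn(6, 3)
    w_obs <- sum(rank(pooled)[1:3])
    ws <- apply(combos, 2, function(i) sum(rank(pooled)[i]))
    lo <- mean(ws <= w_obs); hi <- mean(ws >= w_obs)
    min(1, 2 * min(lo, hi))
  })
  expect_identical(enum_p, 0.1)
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(w$p_value, enum_p)
  expect_true(w$exact)
  # symmetry and identity
  expect_identical(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p_value, 0.1)
  expect_identical(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("shapiro_wilk matches the reference implementation and validates", {
  set.seed(71)
  x <- stats::rlnorm(100)
  ours <- shapiro_wilk(x)
  ref <- stats::shapiro.test(x)
  expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-6)
  expect_lt(abs(ours$p_value - ref$p.value), 1e-6)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  # heavy skew is detected in the large majority of trials
  hits <- sum(vapply(1:50, function(s) {
    set.seed(s)
    shapiro_wilk(stats::rexp(100)^2)$p_value < 0.05
  }, logical(1)))
  expect_gte(hits, 45L)
})

test_that("compare_hypotheses flags dominated hypotheses and no others", {
  set.seed(5)
  ref <- stats::rpois(100, 50)
  worse <- ref + 5          # strict dominance
  same <- ref[sample(100)]  # identical distribution, interleaved
  ct <- cbind(reference = ref, dominated = worse, clone = same)
  class(ct) <- c("cost_table", "matrix")
  cmp <- compare_hypotheses(ct, reference = "reference")
  expect_identical(attr(cmp, "reference"), "reference")
  expect_true(cmp$significant[cmp$hypothesis == "dominated"])
  expect_false(cmp$significant[cmp$hypothesis == "clone"])
  expect_identical(cmp$wilcoxon_p[cmp$hypothesis == "reference"], 1)
  # invariant to column order
  cmp2 <- compare_hypotheses(ct[, c(3, 1, 2)], reference = "reference")
  for (h in colnames(ct)) {
    expect_identical(cmp$significant[cmp$hypothesis == h],
                     cmp2$significant[cmp2$hypothesis == h])
  }
  expect_error(compare_hypotheses(ct[, 1, drop = FALSE]), "two hypotheses")
  expect_error(compare_hypotheses(ct[1:2, ]), "three replicates")
})

test_that("evaluate_hypotheses assembles a replicate-by-hypothesis table", {
  ds <- planted_fungi_dataset(n_families = 20, seed = 67)
  tab <- ds$taxon_table
  bbs <- list(build_backbone("fungi_others", tab),
              build_backbone("opisthokonta_others", tab))
  cfg <- search_config(n_replicates = 3, seed = 23)
  ct <- evaluate_hypotheses(ds$gene_trees, bbs, cfg, tab)
  expect_identical(dim(unclass(ct)), c(3L, 2L))
  expect_identical(colnames(ct), c("fungi_others", "opisthokonta_others"))
  expect_true(all(ct >= 0))
  expect_length(attr(ct, "medians"), 2L)
})
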