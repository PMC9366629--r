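# Fixtures built in code: no data files.

# three-major-clade toy taxonomy used across filter/backbone tests
toy_tab <- function() {
  taxon_table(data.frame(
    taxon_id = c("fun1", "fun2", "met1", "met2", "amo1", "amo2",
                 "dis1", "dis2", "mem1", "anc1"),
    major_clade = c(rep("Opisthokonta", 4), rep("Amoebozoa", 2),
                    rep("Excavata", 3), "Orphan"),
    minor_clade = c("Fungi", "Fungi", "Metazoa", "Metazoa",
                    "Tubulinea", "Tubulinea",
                    "Discoba", "Discoba", "Metamonada", "Ancyromonadida"),
    source = "genome", stringsAsFactors = FALSE))
}

# random rooted binary gene tree over `ns` species with multi-copy leaves
rand_instance <- function(seed, ns_max = 5L, ng_max = 8L) {
  set.seed(seed)
  ns <- sample(3:ns_max, 1L)
  sp <- simulate_species_tree(ns, seed = seed, labels = LETTERS[1:ns])
  ng <- sample(3:ng_max, 1L)
  taxa <- sample(LETTERS[1:ns], ng, replace = TRUE)
  labs <- paste0(taxa, "|", stats::ave(seq_along(taxa), taxa, FUN = seq_along))
  g <- ape::rtree(ng, tip.label = labs, br = NULL)
  list(sp = sp, gene = g)
}

# unrooted variant of the above
rand_unrooted_instance <- function(seed, ns_max = 6L, ng_max = 9L) {
  inst <- rand_instance(seed, ns_max = ns_max, ng_max = ng_max)
  if (ape::Ntip(inst$gene) >= 3L) inst$gene <- ape::unroot(inst$gene)
  inst
}

# drop copy suffixes so gene topology can be compared to the species tree
strip_copies <- function(tree) {
  tree$tip.label <- leaf_taxon(tree$tip.label)
  tree
}

# 12-family presence/absence fixture with known censuses (criterion fixture
# for the metazoan/fungal subsetting rules); counts chosen so exactly
# families 1-3 have >= 10 Metazoa and >= 10 Fungi, and families 4-6 have
# >= 10 Metazoa and no Fungi
subset_fixture <- function() {
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
  m <- matrix(0L, nrow = 12, ncol = length(taxa),
              dimnames = list(sprintf("fam%02d", 1:12), taxa))
  for (i in 1:12) {
    if (n_met[i] > 0) m[i, sprintf("met%02d", seq_len(n_met[i]))] <- 1L
    if (n_fun[i] > 0) m[i, sprintf("fun%02d", seq_len(n_fun[i]))] <- 1L
    if (n_amo[i] > 0) m[i, sprintf("amo%02d", seq_len(n_amo[i]))] <- 1L
  }
  list(tab = tab, counts = m,
       both10 = sprintf("fam%02d", 1:3),      # >=10 Metazoa and >=10 Fungi
       met10_nofun = sprintf("fam%02d", 4:6)) # >=10 Metazoa and 0 Fungi
}

# planted-root dataset over the toy taxonomy: true root between Fungi and
# everything else (so the Opisthokonta hypothesis is wrong but close)
planted_fungi_dataset <- function(n_families = 60L, seed = 42L,
                                  dup_rate = 0.2, loss_rate = 0.2,
                                  retention = 1) {
  tab <- toy_tab()
  truth <- read_newick(paste0(
    "((fun1,fun2),(((met1,met2),(amo1,amo2)),",
    "((dis1,dis2),(mem1,anc1))));"))
  p <- sim_params(n_taxa = 10, dup_rate = dup_rate, loss_rate = loss_rate,
                  n_families = n_families, retention = retention, seed = seed)
  ds <- simulate_dataset(p, species_tree = truth, taxon_table = tab)
  ds
}
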