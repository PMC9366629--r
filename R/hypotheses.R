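# Named root hypotheses as backbone constraints, their constrained optimal
# costs across replicates, and rank-based statistical comparison (Shapiro-Wilk
# normality screen, then Wilcoxon rank-sum against a reference hypothesis at
# alpha = 0.05, uncorrected by default).

#' Build a backbone constraint encoding a root hypothesis
#'
#' Built-in hypothesis ids: `fungi_others`, `opisthokonta_others`,
#' `discoba_others`, `unikonta_bikonta` and
#' `ancyromonadida_metamonada_others`. Each places one named group as a child
#' of the root versus everything else; relationships within each side are
#' unconstrained. Arbitrary hypotheses are given as a named list of taxon-id
#' groups plus an optional topology over group names.
#'
#' @param spec a built-in id, or a list with `hypothesis_id`, `groups` (named
#'   list of taxon-id vectors) and optional `topology` (nested list of group
#'   names; default: flat root over the groups)
#' @param tab a [taxon_table()]
#' @param taxa the analysis taxon set (default: all table taxa)
#' @param unikonta major clades composing Unikonta for `unikonta_bikonta`
#'   (composition is configuration, not biology settled in code)
#' @return a `backbone` object
#' @export
build_backbone <- function(spec, tab, taxa = tab$taxon_id,
                           unikonta = c("Opisthokonta", "Amoebozoa")) {
  named_side <- function(members) {
    side <- sort(intersect(members, taxa))
    if (!length(side)) stop("hypothesis group resolves to no analysis taxa")
    rest <- sort(setdiff(taxa, side))
    if (!length(rest)) stop("hypothesis group swallows every analysis taxon")
    list(side, rest)
  }
  if (is.character(spec) && length(spec) == 1L) {
    id <- spec
    grp <- switch(spec,
      fungi_others = named_side(clade_taxa(tab, "Fungi")),
      opisthokonta_others = named_side(clade_taxa(tab, "Opisthokonta")),
      discoba_others = named_side(clade_taxa(tab, "Discoba")),
      unikonta_bikonta = named_side(unlist(lapply(unikonta, clade_taxa,
                                                  tab = tab))),
      ancyromonadida_metamonada_others = named_side(
        c(clade_taxa(tab, "Ancyromonadida"), clade_taxa(tab, "Metamonada"))),
      stop("unknown built-in hypothesis: ", spec))
    groups <- stats::setNames(grp, c(id, "others"))
    topology <- list(id, "others")
  } else {
    if (is.null(spec$groups) || is.null(spec$hypothesis_id))
      stop("custom hypothesis needs hypothesis_id and groups")
    id <- spec$hypothesis_id
    groups <- lapply(spec$groups, function(g) sort(intersect(g, taxa)))
    if (any(!lengths(groups))) stop("hypothesis group resolves to no analysis taxa")
    topology <- if (is.null(spec$topology)) as.list(names(groups))
                else spec$topology
  }
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("hypothesis groups overlap: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  if (!setequal(flat, taxa))
    stop("hypothesis groups must partition the analysis taxa; missing: ",
         paste(setdiff(taxa, flat), collapse = ", "))
  required <- character(0)
  rec <- function(node) {
    if (is.character(node)) return(groups[[node]])
    lv <- unlist(lapply(node, rec), use.names = FALSE)
    required <<- c(required, paste(sort(lv), collapse = ","))
    lv
  }
  all_lv <- rec(topology)
  required <- c(required,
                vapply(groups[lengths(groups) > 1L],
                       function(g) paste(sort(g), collapse = ","), character(1)))
  required <- setdiff(unique(required), paste(sort(taxa), collapse = ","))
  structure(list(hypothesis_id = id, groups = groups, topology = topology,
                 free_within = TRUE, required_keys = required, taxa = sort(taxa)),
            class = "backbone")
}

#' Is a species tree consistent with a backbone?
#' @param tree rooted binary phylo
#' @param backbone a [build_backbone()]
#' @return logical
#' @export
backbone_consistent <- function(tree, backbone) {
  constraint_ok_cl(phylo_to_clist(tree), backbone)
}

#' Constrained optimal costs per replicate and hypothesis
#'
#' For each replicate seed and each backbone, a constrained hill climb yields
#' the minimum total cost; results are assembled into a replicate x
#' hypothesis cost table.
#'
#' @param gene_trees named list of phylo objects
#' @param backbones list of [build_backbone()] objects
#' @param config a [search_config()] (its `constraint` field is overridden
#'   per hypothesis; `n_replicates` gives the rows)
#' @param taxon_table a [taxon_table()]
#' @return a `cost_table`: numeric matrix (replicates x hypotheses) with
#'   attributes `medians` and `config_seed`
#' @export
evaluate_hypotheses <- function(gene_trees, backbones, config, taxon_table) {
  ids <- vapply(backbones, `[[`, character(1), "hypothesis_id")
  if (anyDuplicated(ids)) stop("duplicate hypothesis ids")
  m <- matrix(NA_real_, nrow = config$n_replicates, ncol = length(backbones),
              dimnames = list(NULL, ids))
  for (j in seq_along(backbones)) {
    cfg <- config
    cfg$constraint <- backbones[[j]]
    cfg$seed <- derive_seed(config$seed, "hypothesis", ids[j])
    res <- run_replicates(gene_trees, cfg, taxon_table)
    m[, j] <- res$records$total_cost
  }
  structure(m, medians = apply(m, 2, stats::median),
            config_seed = config$seed, class = c("cost_table", "matrix"))
}

# ---- statistics -------------------------------------------------------------

#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper around [stats::shapiro.test()].
#' @param values numeric vector, n >= 3, non-constant
#' @return list with `statistic` (W) and `p_value`
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3L) stop("Shapiro-Wilk needs n >= 3")
  if (stats::sd(values) == 0) stop("Shapiro-Wilk is undefined for constant data")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p for small tie-free samples, normal approximation with tie and
#' continuity correction otherwise ([stats::wilcox.test()] semantics).
#' @param x,y numeric samples (non-empty)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return list with `statistic` (W, rank-sum of `x` minus its minimum),
#'   `p_value` and `exact`
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) < 50 && length(y) < 50
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Compare hypothesis cost distributions against a reference
#'
#' Shapiro-Wilk per hypothesis (normality screen motivating the rank-based
#' comparison), then a pairwise Wilcoxon rank-sum of every hypothesis against
#' the reference, flagged at `alpha`. No multiple-testing correction by
#' default; Holm available.
#'
#' @param cost_table matrix replicates x hypotheses (see
#'   [evaluate_hypotheses()])
#' @param reference hypothesis id to compare against (default: the lowest
#'   median cost)
#' @param alpha significance level
#' @param holm apply Holm correction to the Wilcoxon p values?
#' @return a `comparison_result` data.frame: `hypothesis`, `median_cost`,
#'   `shapiro_W`, `shapiro_p`, `wilcoxon_W`, `wilcoxon_p`, `significant`
#' @export
compare_hypotheses <- function(cost_table, reference = NULL, alpha = 0.05,
                               holm = FALSE) {
  if (ncol(cost_table) < 2L) stop("need at least two hypotheses")
  if (nrow(cost_table) < 3L) stop("need at least three replicates")
  meds <- apply(cost_table, 2, stats::median)
  if (is.null(reference)) reference <- colnames(cost_table)[which.min(meds)]
  if (!reference %in% colnames(cost_table))
    stop("unknown reference hypothesis: ", reference)
  ref <- cost_table[, reference]
  rows <- lapply(colnames(cost_table), function(h) {
    sw <- tryCatch(shapiro_wilk(cost_table[, h]),
                   error = function(e) list(statistic = NA_real_,
                                            p_value = NA_real_))
    if (h == reference) {
      wt <- list(statistic = NA_real_, p_value = 1)
    } else {
      wt <- wilcoxon_rank_sum(cost_table[, h], ref)
    }
    data.frame(hypothesis = h, median_cost = meds[[h]],
               shapiro_W = sw$statistic, shapiro_p = sw$p_value,
               wilcoxon_W = wt$statistic, wilcoxon_p = wt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p <- out$wilcoxon_p
  if (holm) {
    i <- out$hypothesis != reference
    p[i] <- stats::p.adjust(p[i], method = "holm")
  }
  out$wilcoxon_p_adj <- p
  out$significant <- out$hypothesis != reference & p < alpha
  attr(out, "reference") <- reference
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}
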