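# Association statistics linking ortholog presence/absence to a binary
# phenotype: Fisher/Bonferroni, permutation null, tree-aware
# contrasting-pairs test, feature selection, Ward clustering.

#' Contingency counts for one ortholog family
#'
#' Counts over labeled strains only: `a` = phenotype-positive strains with
#' the gene, `b` = positive without, `c` = negative with, `d` = negative
#' without.
#'
#' @param matrix an [ortholog_matrix()].
#' @param phenotypes a [phenotype_table()].
#' @param family_id family column to count.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
contingency_counts <- function(matrix, phenotypes, family_id) {
  if (!family_id %in% colnames(matrix))
    stop("unknown family id: ", family_id)
  ph <- phenotypes[match(rownames(matrix), phenotypes$strain_id), ]
  lab <- ph$label
  keep <- !is.na(lab) & lab != "unknown"
  if (!any(keep)) stop("no labeled strains")
  g <- matrix[keep, family_id]
  pos <- lab[keep] == "positive"
  c(a = sum(g == 1L & pos), b = sum(g == 0L & pos),
    c = sum(g == 1L & !pos), d = sum(g == 0L & !pos))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-ordering definition: the p-value is the sum of probabilities
#' of all hypergeometric tables (at the observed margins) whose probability
#' does not exceed that of the observed table. A table with an empty row or
#' column margin is degenerate: p = 1 with attribute `degenerate = TRUE`.
#'
#' @param counts integer vector `c(a, b, c, d)` as from
#'   [contingency_counts()].
#' @return p-value in (0, 1].
#' @export
fisher_two_sided <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 4L || any(counts < 0L)) stop("need 4 non-negative counts")
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) {
    p <- 1.0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  probs <- dhyper(x, c1, n - c1, r1)
  pobs <- dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param n_tests number of tests (>= 1).
#' @return `min(1, p * n_tests)`.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  pmin(1, p * n_tests)
}

.tip_types <- function(gene, trait) {
  # 1 = (1,1), 2 = (0,0), 3 = (1,0), 4 = (0,1)
  ifelse(gene == 1L, ifelse(trait == 1L, 1L, 3L),
         ifelse(trait == 1L, 4L, 2L))
}

#' Maximum edge-disjoint contrasting pairs on a strain tree
#'
#' A contrasting pair is two tips differing in both gene and trait state;
#' pairs within one pairing must have edge-disjoint tip-to-tip paths, making
#' them phylogenetically independent observations of a gene-trait
#' co-change. The maximum number of such pairs, together with the maximum
#' and minimum number of *supporting* pairs (gene and trait co-change in the
#' same direction) among all maximum pairings, is computed by a post-order
#' dynamic program; multifurcations are handled natively.
#'
#' @param tree a rooted `phylo` object.
#' @param gene,trait named 0/1 vectors over all tips.
#' @return named integer vector `c(n_pairs, s_max, s_min)`.
#' @export
max_contrasting_pairs <- function(tree, gene, trait) {
  tips <- tree$tip.label
  if (!all(tips %in% names(gene)) || !all(tips %in% names(trait)))
    stop("every tip needs both a gene and a trait state")
  g <- as.integer(gene[tips]); tr <- as.integer(trait[tips])
  if (anyNA(g) || anyNA(tr)) stop("tip missing a state")
  types <- .tip_types(g, tr)
  res <- .pairs_dp_cpp(tree$edge, length(tips), as.integer(types))
  c(n_pairs = res[1], s_max = res[2], s_min = res[3])
}

#' Binomial p-values for the contrasting-pairs test
#'
#' Under the null of no association, each independent contrasting pair
#' supports the association with probability 1/2. `best_p` is the upper
#' binomial tail at the most favourable maximum pairing (`s_max`),
#' `worst_p` at the least favourable (`s_min`). Zero pairs gives p = 1.
#'
#' @param n_pairs,s_max,s_min as returned by [max_contrasting_pairs()].
#' @return named numeric vector `c(best_p, worst_p)`.
#' @export
pairwise_binomial_pvalues <- function(n_pairs, s_max, s_min) {
  if (!(0 <= s_min && s_min <= s_max && s_max <= n_pairs))
    stop("need 0 <= s_min <= s_max <= n_pairs")
  if (n_pairs == 0) return(c(best_p = 1.0, worst_p = 1.0))
  tail_p <- function(s) pbinom(s - 1, n_pairs, 0.5, lower.tail = FALSE)
  c(best_p = tail_p(s_max), worst_p = tail_p(s_min))
}

.abs_log_or <- function(a, b, c, d) {
  abs(log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))))
}

#' Label-permutation p-value for one family
#'
#' Phenotype labels are permuted uniformly among the labeled strains (label
#' counts preserved) and the association statistic recomputed; the p-value
#' uses the add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)`. The
#' default statistic is the maximum supporting-pair count `s_max` from
#' [max_contrasting_pairs()] (tree-aware); `"odds_ratio"` uses the absolute
#' Haldane-corrected log odds ratio and requires no tree.
#'
#' @param matrix an [ortholog_matrix()].
#' @param phenotypes a [phenotype_table()].
#' @param tree rooted `phylo` (required for the `"pairs"` statistic).
#' @param family_id family column.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param statistic `"pairs"` or `"odds_ratio"`.
#' @param tie_break `"none"` keeps the conservative tie-inclusive estimator
#'   (valid: P(p <= alpha) <= alpha, but super-uniform when the statistic
#'   is discrete); `"randomized"` breaks ties uniformly
#'   (`p = (#\{> obs\} + U * (1 + #\{= obs\})) / (1 + n_perm)`), which is
#'   exactly Uniform(0, 1) under the exchangeable null.
#' @return p-value; attribute `constant = TRUE` flags a statistic invariant
#'   across all permutations.
#' @export
permutation_pvalue <- function(matrix, phenotypes, tree = NULL, family_id,
                               n_perm = 199L, seed = 1L,
                               statistic = c("pairs", "odds_ratio"),
                               tie_break = c("none", "randomized")) {
  statistic <- match.arg(statistic)
  tie_break <- match.arg(tie_break)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  ph <- phenotypes[match(rownames(matrix), phenotypes$strain_id), ]
  keep <- !is.na(ph$label) & ph$label != "unknown"
  g <- matrix[keep, family_id]
  y <- as.integer(ph$label[keep] == "positive")
  ids <- rownames(matrix)[keep]
  set.seed(as.integer(seed))
  perms <- vapply(seq_len(n_perm), function(i) sample(y), integer(length(y)))
  if (statistic == "pairs") {
    if (is.null(tree)) stop("the pairs statistic requires a tree")
    sub <- ape::keep.tip(tree, intersect(tree$tip.label, ids))
    ord <- match(sub$tip.label, ids)
    obs <- max_contrasting_pairs(sub, setNames(g, ids), setNames(y, ids))[["s_max"]]
    types <- vapply(seq_len(n_perm), function(i)
      .tip_types(g[ord], perms[ord, i]), integer(length(ord)))
    stat <- .pairs_dp_batch_cpp(sub$edge, length(sub$tip.label),
                                matrix(types, nrow = length(ord)))
  } else {
    cnt <- function(yy) c(sum(g == 1L & yy == 1L), sum(g == 0L & yy == 1L),
                          sum(g == 1L & yy == 0L), sum(g == 0L & yy == 0L))
    o <- cnt(y); obs <- .abs_log_or(o[1], o[2], o[3], o[4])
    n1 <- colSums(perms * g)          # a per permutation
    npos <- sum(y); ngene <- sum(g)
    stat <- .abs_log_or(n1, npos - n1, ngene - n1,
                        length(y) - npos - ngene + n1)
  }
  n_gt <- sum(stat > obs + 1e-12)
  n_eq <- sum(abs(stat - obs) <= 1e-12)
  p <- if (tie_break == "randomized")
    (n_gt + runif(1) * (1 + n_eq)) / (1 + n_perm)
  else (1 + n_gt + n_eq) / (1 + n_perm)
  if (all(abs(stat - stat[1]) < 1e-12) && abs(stat[1] - obs) < 1e-12) {
    if (tie_break == "none") p <- 1.0
    attr(p, "constant") <- TRUE
  }
  p
}

#' Run all association tests over every ortholog family
#'
#' Computes, per family: contingency counts, two-sided Fisher p with
#' Bonferroni adjustment (multiplier = number of families tested, i.e. the
#' full matrix width, overridable), a label-permutation p-value, and the
#' tree-aware contrasting-pairs test with its best/worst binomial p-values.
#'
#' @param matrix an [ortholog_matrix()].
#' @param phenotypes a [phenotype_table()]; unknown labels are excluded.
#' @param tree optional rooted `phylo`; without it the pairwise columns are
#'   `NA` and the permutation statistic falls back to the odds ratio.
#' @param n_perm permutations per family.
#' @param seed base RNG seed; family `i` uses `seed + i`.
#' @param n_tests Bonferroni multiplier, default `ncol(matrix)`.
#' @param statistic permutation statistic, see [permutation_pvalue()].
#' @return data.frame of class `pangwas_result`, one row per family.
#' @export
run_pangwas <- function(matrix, phenotypes, tree = NULL, n_perm = 199L,
                        seed = 1L, n_tests = ncol(matrix),
                        statistic = c("pairs", "odds_ratio")) {
  statistic <- match.arg(statistic)
  if (is.null(tree) && statistic == "pairs") statistic <- "odds_ratio"
  al <- align_matrix_phenotypes(matrix, phenotypes)
  m <- al$matrix; ph <- al$phenotypes
  fams <- colnames(m)
  y <- as.integer(ph$label == "positive")
  ids <- rownames(m)
  sub <- NULL
  if (!is.null(tree)) {
    miss <- setdiff(ids, tree$tip.label)
    if (length(miss)) stop("strains absent from tree: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    sub <- ape::keep.tip(tree, ids)
  }
  res <- lapply(seq_along(fams), function(i) {
    cc <- contingency_counts(m, ph, fams[i])
    fp <- fisher_two_sided(cc)
    pp <- permutation_pvalue(m, ph, tree = sub, family_id = fams[i],
                             n_perm = n_perm, seed = as.integer(seed) + i,
                             statistic = statistic)
    if (!is.null(sub)) {
      mp <- max_contrasting_pairs(sub, setNames(m[, i], ids), setNames(y, ids))
      bp <- pairwise_binomial_pvalues(mp[1], mp[2], mp[3])
    } else {
      mp <- c(n_pairs = NA_integer_, s_max = NA_integer_, s_min = NA_integer_)
      bp <- c(best_p = NA_real_, worst_p = NA_real_)
    }
    data.frame(family_id = fams[i], a = cc[1], b = cc[2], c = cc[3], d = cc[4],
               fisher_p = as.numeric(fp),
               permutation_p = as.numeric(pp),
               n_pairs = mp[1], s_max = mp[2], s_min = mp[3],
               best_pairwise_p = bp[1], worst_pairwise_p = bp[2],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$bonferroni_p <- bonferroni_adjust(out$fisher_p, n_tests)
  attr(out, "n_tests") <- n_tests
  class(out) <- c("pangwas_result", "data.frame")
  out
}

#' Select phenotype-associated features
#'
#' The selected set is the union of families significant by Bonferroni-
#' corrected Fisher test, by permutation test, by the worst-case
#' contrasting-pairs test (all at `alpha`), plus families implicated by
#' mutagenesis. Each selected feature carries all applicable evidence
#' flags; the output is ordered by family id, making it invariant to the
#' input row order.
#'
#' @param results a `pangwas_result` from [run_pangwas()].
#' @param alpha significance level in (0, 1).
#' @param mutagenesis_ids family ids with experimental knockout evidence.
#' @return data.frame with `family_id` and logical columns `fisher`,
#'   `permutation`, `pairwise`, `mutagenesis`.
#' @export
select_sc_features <- function(results, alpha = 0.05,
                               mutagenesis_ids = character()) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  fisher_ids <- results$family_id[results$bonferroni_p <= alpha]
  perm_ids <- results$family_id[results$permutation_p <= alpha]
  pair_ids <- results$family_id[!is.na(results$worst_pairwise_p) &
                                  results$worst_pairwise_p <= alpha]
  all_ids <- sort(unique(c(fisher_ids, perm_ids, pair_ids,
                           as.character(mutagenesis_ids))))
  data.frame(family_id = all_ids,
             fisher = all_ids %in% fisher_ids,
             permutation = all_ids %in% perm_ids,
             pairwise = all_ids %in% pair_ids,
             mutagenesis = all_ids %in% mutagenesis_ids,
             stringsAsFactors = FALSE)
}

#' Ward clustering of binary feature columns
#'
#' Agglomerative clustering of feature presence/absence profiles with
#' Ward's criterion on Euclidean distances (`hclust` method `ward.D2`).
#'
#' @param features a [feature_table()] or binary matrix (features in
#'   columns).
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (NULL for a single feature) and `clusters`
#'   (named integer vector when `k` is given or only one feature exists).
#' @export
cluster_features_ward <- function(features, k = NULL) {
  x <- t(unclass(as.matrix(features)))
  if (nrow(x) == 1L)
    return(list(hclust = NULL, clusters = setNames(1L, rownames(x))))
  hc <- hclust(dist(x), method = "ward.D2")
  clusters <- if (!is.null(k)) cutree(hc, k = k) else NULL
  list(hclust = hc, clusters = clusters)
}
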