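# Independent brute-force oracles used across the suite.

# table probability from first principles (binomial coefficients), and the
# probability-ordering two-sided p by exhaustive enumeration
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d; r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1.0)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  prob <- function(x) exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) -
                            lchoose(n, c1))
  ps <- vapply(lo:hi, prob, 0)
  pobs <- prob(a)
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]))
}

# all edges on the path between two tips (as "a-b" keys)
.path_edges <- function(tree, i, j) {
  np <- ape::nodepath(tree, i, j)
  paste(pmin(np[-1], np[-length(np)]), pmax(np[-1], np[-length(np)]))
}

# brute-force enumeration of all edge-disjoint contrasting pairings
oracle_pairs <- function(tree, gene, trait) {
  tips <- tree$tip.label
  g <- gene[tips]; tr <- trait[tips]
  n <- length(tips)
  cand <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (g[i] != g[j] && tr[i] != tr[j]) {
      supporting <- (g[i] == tr[i]) && (g[j] == tr[j])
      cand[[length(cand) + 1]] <- list(edges = .path_edges(tree, i, j),
                                       supp = supporting)
    }
  }
  best <- c(n_pairs = 0L, s_max = 0L, s_min = 0L)
  rec <- function(k, used, npair, nsupp) {
    if (npair > best[["n_pairs"]]) {
      best <<- c(n_pairs = npair, s_max = nsupp, s_min = nsupp)
    } else if (npair == best[["n_pairs"]]) {
      best[["s_max"]] <<- max(best[["s_max"]], nsupp)
      best[["s_min"]] <<- min(best[["s_min"]], nsupp)
    }
    if (k > length(cand)) return()
    for (m in k:length(cand)) {
      e <- cand[[m]]$edges
      if (!any(e %in% used))
        rec(m + 1, c(used, e), npair + 1L, nsupp + cand[[m]]$supp)
    }
  }
  rec(1L, character(0), 0L, 0L)
  best
}

# all-pairs concordance count
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (i in seq_along(sp)) for (j in seq_along(sn)) {
    tot <- tot + if (sp[i] > sn[j]) 1 else if (sp[i] == sn[j]) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# random labeled tree for the pairs property test
random_labeled_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  list(tree = tr,
       gene = setNames(sample(0:1, n_tips, TRUE), tr$tip.label),
       trait = setNames(sample(0:1, n_tips, TRUE), tr$tip.label))
}

# tiny deterministic study used by several suites
small_study <- function(seed = 11L) {
  simulate_sc_study(sim_config(n_strains = 40L, n_families = 40L,
                               n_causal = 8L, threshold = 4L,
                               seq_len = 40L, seed = seed))
}
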