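test_that("contingency counts cover labeled strains only", {
  m <- ortholog_matrix(rbind(s1 = c(1L, 1L), s2 = c(1L, 0L),
                             s3 = c(0L, 1L), s4 = c(0L, 0L), s5 = c(1L, 1L)),
                       paste0("s", 1:5), c("f1", "f2"))
  ph <- phenotype_table(paste0("s", 1:5),
                        c("positive", "positive", "negative", "negative",
                          "unknown"))
  expect_identical(contingency_counts(m, ph, "f1"),
                   c(a = 2L, b = 0L, c = 0L, d = 2L))
  expect_error(contingency_counts(m, ph, "nope"), "unknown family")
  m2 <- ortholog_matrix(matrix(1L, 4, 1), paste0("s", 1:4), "f")
  ph2 <- phenotype_table(paste0("s", 1:4),
                         c("positive", "positive", "negative", "negative"))
  cc <- contingency_counts(m2, ph2, "f")
  expect_identical(unname(cc[c("b", "d")]), c(0L, 0L))
})

test_that("two-sided Fisher matches enumeration and handles degeneracy", {
  expect_equal(fisher_two_sided(c(10, 0, 0, 10)), 1.082509e-05,
               tolerance = 1e-6)
  expect_equal(fisher_two_sided(c(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_two_sided(c(1, 0, 0, 1)), 1.0)
  dg <- fisher_two_sided(c(0, 0, 3, 4))
  expect_equal(as.numeric(dg), 1.0)
  expect_true(attr(dg, "degenerate"))
  # exhaustive agreement with the first-principles oracle on small tables
  for (n in c(6L, 11L)) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    combos <- combos[rowSums(combos) <= n, ]
    for (k in seq_len(nrow(combos))) {
      a <- combos$a[k]; b <- combos$b[k]; c <- combos$c[k]
      d <- n - a - b - c
      expect_equal(as.numeric(fisher_two_sided(c(a, b, c, d))),
                   oracle_fisher(a, b, c, d), tolerance = 1e-10)
    }
  }
  # and with fisher.test as a second, independent implementation
  set.seed(3)
  for (k in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(as.numeric(fisher_two_sided(as.vector(t(tab)))),
                 stats::fisher.test(matrix(c(tab[1, 1], tab[2, 1],
                                             tab[1, 2], tab[2, 2]), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Bonferroni adjustment multiplies and clamps", {
  expect_equal(bonferroni_adjust(1e-4, 199), 0.0199)
  expect_equal(bonferroni_adjust(0.01, 200), 1.0)
  expect_equal(bonferroni_adjust(0.7, 1), 0.7)
  expect_error(bonferroni_adjust(0.5, 0), "n_tests")
})

test_that("contrasting-pairs DP reproduces hand-checkable cases", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_identical(max_contrasting_pairs(tr2, c(A = 1, B = 0), c(A = 1, B = 0)),
                   c(n_pairs = 1L, s_max = 1L, s_min = 1L))
  tr4 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(
    max_contrasting_pairs(tr4, c(A = 1, B = 0, C = 1, D = 0),
                          c(A = 1, B = 0, C = 1, D = 0)),
    c(n_pairs = 2L, s_max = 2L, s_min = 2L))
  expect_identical(
    max_contrasting_pairs(tr4, c(A = 1, B = 1, C = 1, D = 1),
                          c(A = 1, B = 0, C = 1, D = 0)),
    c(n_pairs = 0L, s_max = 0L, s_min = 0L))
  expect_error(max_contrasting_pairs(tr4, c(A = 1, B = 0), c(A = 1, B = 0)),
               "gene and a trait")
})

test_that("contrasting-pairs DP equals brute-force enumeration", {
  for (k in 1:120) {
    n_tips <- sample(3:8, 1)
    inst <- random_labeled_tree(n_tips, seed = 1000 + k)
    dp <- max_contrasting_pairs(inst$tree, inst$gene, inst$trait)
    bf <- oracle_pairs(inst$tree, inst$gene, inst$trait)
    expect_identical(unname(dp), unname(as.integer(bf)),
                     label = sprintf("case %d (%d tips)", k, n_tips))
  }
  # multifurcations handled natively
  star <- ape::read.tree(text = "(A,B,C,D,E,F);")
  g <- setNames(c(1, 1, 1, 0, 0, 0), star$tip.label)
  expect_identical(max_contrasting_pairs(star, g, g),
                   c(n_pairs = 3L, s_max = 3L, s_min = 3L))
})

test_that("pairwise binomial tails follow the fair-coin null", {
  expect_equal(pairwise_binomial_pvalues(2, 2, 2),
               c(best_p = 0.25, worst_p = 0.25))
  expect_equal(pairwise_binomial_pvalues(0, 0, 0),
               c(best_p = 1.0, worst_p = 1.0))
  expect_equal(pairwise_binomial_pvalues(5, 5, 5),
               c(best_p = 0.03125, worst_p = 0.03125))
  bw <- pairwise_binomial_pvalues(7, 6, 2)
  expect_lte(bw[["best_p"]], bw[["worst_p"]])
  expect_error(pairwise_binomial_pvalues(2, 1, 2))
})

test_that("permutation p-values are deterministic, floored and flagged", {
  st <- small_study()
  fam <- st$causal_ids[1]
  p1 <- permutation_pvalue(st$matrix, st$phenotypes, st$tree, fam,
                           n_perm = 99L, seed = 5L)
  p2 <- permutation_pvalue(st$matrix, st$phenotypes, st$tree, fam,
                           n_perm = 99L, seed = 5L)
  expect_identical(p1, p2)
  # a constant gene column has a label-invariant statistic
  m <- unclass(st$matrix)
  m[, 1] <- 1L
  mc <- ortholog_matrix(m)
  pc <- permutation_pvalue(mc, st$phenotypes, st$tree, colnames(mc)[1],
                           n_perm = 49L, seed = 2L)
  expect_equal(as.numeric(pc), 1.0)
  expect_true(attr(pc, "constant"))
  # strongly associated family on a clean dataset hits the 1/(N+1) floor
  mm <- ortholog_matrix(matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1),
                        paste0("s", 1:20), "f")
  php <- phenotype_table(paste0("s", 1:20),
                         rep(c("positive", "negative"), each = 10))
  pf <- permutation_pvalue(mm, php, tree = NULL, "f", n_perm = 999L,
                           seed = 3L, statistic = "odds_ratio")
  expect_equal(as.numeric(pf), 1 / 1000)
})

test_that("feature selection unions evidence streams deterministically", {
  mk <- function(id, bonf, perm, worst) {
    data.frame(family_id = id, bonferroni_p = bonf, permutation_p = perm,
               worst_pairwise_p = worst, stringsAsFactors = FALSE)
  }
  res <- rbind(mk(c("a", "b", "c"), 0.01, 1, 1),       # fisher only
               mk(c("d", "e"), 1, 0.01, 1),            # permutation only
               mk("f", 1, 1, 0.01),                    # pairwise only
               mk("g", 1, 1, 1))                       # mutagenesis only
  sel <- select_sc_features(res, alpha = 0.05, mutagenesis_ids = "g")
  expect_identical(sel$family_id, c("a", "b", "c", "d", "e", "f", "g"))
  expect_identical(sum(sel$fisher), 3L)
  expect_identical(sum(sel$mutagenesis), 1L)
  # fully overlapping evidence: idempotent union, all flags set
  res2 <- mk(paste0("x", 1:5), 0.01, 0.01, 0.01)
  sel2 <- select_sc_features(res2, mutagenesis_ids = paste0("x", 1:5))
  expect_identical(nrow(sel2), 5L)
  expect_true(all(sel2$fisher & sel2$permutation & sel2$pairwise &
                    sel2$mutagenesis))
  # invariant to input order
  sel3 <- select_sc_features(res[sample(nrow(res)), ], alpha = 0.05,
                             mutagenesis_ids = "g")
  expect_identical(sel3, sel)
})

test_that("Ward clustering separates orthogonal feature blocks", {
  set.seed(8)
  block1 <- matrix(rep(c(1L, 0L), c(10, 10)), 20, 5)
  block2 <- matrix(rep(c(0L, 1L), c(10, 10)), 20, 5)
  ft <- feature_table(cbind(block1, block2), paste0("g", 1:20),
                      paste0("f", 1:10))
  cl <- cluster_features_ward(ft, k = 2)
  expect_identical(length(unique(cl$clusters[1:5])), 1L)
  expect_identical(length(unique(cl$clusters[6:10])), 1L)
  expect_false(cl$clusters[1] == cl$clusters[6])
  # identical columns merge at height zero first
  ft2 <- feature_table(cbind(block1[, 1:2], block2[, 1]), paste0("g", 1:20),
                       c("f1", "f2", "f3"))
  hc <- cluster_features_ward(ft2)$hclust
  expect_equal(hc$height[1], 0)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  # single feature: singleton cluster, no error
  one <- cluster_features_ward(feature_table(block1[, 1, drop = FALSE],
                                             paste0("g", 1:20), "f1"))
  expect_identical(unname(one$clusters), 1L)
})

test_that("run_pangwas produces coherent per-family results", {
  st <- small_study()
  gw <- run_pangwas(st$matrix, st$phenotypes, tree = st$tree, n_perm = 49L,
                    seed = 3L)
  expect_identical(nrow(gw), ncol(st$matrix))
  expect_true(all(gw$bonferroni_p >= gw$fisher_p - 1e-12))
  ok <- !is.na(gw$best_pairwise_p)
  expect_true(all(gw$best_pairwise_p[ok] <= gw$worst_pairwise_p[ok] + 1e-12))
  expect_true(all(gw$fisher_p > 0 & gw$fisher_p <= 1))
  expect_true(all(gw$permutation_p > 0 & gw$permutation_p <= 1))
  expect_true(all(gw$a + gw$b + gw$c + gw$d ==
                    sum(st$phenotypes$label != "unknown")))
})
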