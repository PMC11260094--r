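test_that("band assignment is a pure strict-inequality function of score", {
  b <- sc_bands(upper = 0.68, lower = 0.39)
  grid <- (0:500) / 500
  band <- classify_score(grid, b)
  expect_identical(band[grid > 0.68], rep("likely_positive", sum(grid > 0.68)))
  expect_identical(band[grid < 0.39], rep("likely_negative", sum(grid < 0.39)))
  expect_identical(band[grid >= 0.39 & grid <= 0.68],
                   rep("putative", sum(grid >= 0.39 & grid <= 0.68)))
  # equality falls into the putative band
  expect_identical(classify_score(c(0.68, 0.39), b),
                   c("putative", "putative"))
  # reference scores from the validation table land in the expected bands
  expect_identical(classify_score(c(0.96, 0.25, 0.60), b),
                   c("likely_positive", "likely_negative", "putative"))
  expect_error(sc_bands(upper = 0.3, lower = 0.5), "lower < upper")
})

test_that("score bands derive from negative and gram-negative extremes", {
  scores <- c(0.1, 0.3, 0.68, 0.39, 0.8, 0.9, 0.5)
  labels <- c("negative", "negative", "negative",
              "positive", "positive", "positive", "positive")
  gram <- c(rep("negative", 6), "positive")
  b <- derive_score_bands(scores, labels, gram)
  expect_equal(b$upper, 0.68)
  expect_equal(b$lower, 0.39)
  # fully separated classes collapse to a flagged midpoint cut
  b2 <- derive_score_bands(c(0.1, 0.2, 0.8, 0.9),
                           c("negative", "negative", "positive", "positive"),
                           rep("negative", 4))
  expect_true(attr(b2, "degenerate"))
  expect_equal(b2$upper, 0.5)
  expect_equal(b2$lower, 0.5)
  expect_error(derive_score_bands(c(0.5, 0.6), c("positive", "positive"),
                                  rep("negative", 2)), "no labeled-negative")
  expect_warning(derive_score_bands(scores, labels, NULL), "gram")
})

test_that("discordant negatives are flagged above a strict threshold", {
  d <- list(X = rbind(diag(2L)[rep(1:2, each = 6), ]))
  set.seed(1)
  X <- cbind(sig = rep(c(1L, 0L), each = 10),
             matrix(rbinom(60, 1, 0.5), 20, 3))
  rownames(X) <- paste0("s", 1:20)
  y <- rep(c("positive", "negative"), each = 10)
  # mislabel one strain whose features look positive
  y[11] <- "negative"; X[11, "sig"] <- 1L
  f <- suppressMessages(train_forest(X, y, n_trees = 200L, seed = 2L))
  flagged <- flag_discordant_negatives(f, y, threshold = 0.6)
  expect_true("s11" %in% flagged)
  expect_false(any(paste0("s", 12:20) %in% flagged))
  # nothing flagged when the threshold exceeds every score
  expect_identical(flag_discordant_negatives(f, y, threshold = 1),
                   character(0))
})

test_that("rank-based AUC matches the concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(17)
  for (k in 1:20) {
    n <- sample(5:200, 1)
    s <- sample(seq(0, 1, by = 0.05), n, TRUE)   # many ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, y), oracle_auc(s, y == 1), tolerance = 1e-12)
  }
})

test_that("stratified holdout reproduces the 78/39 split arithmetic", {
  set.seed(5)
  X <- matrix(rbinom(117 * 20, 1, 0.5), 117, 20)
  y <- c(rep(1L, 86), rep(0L, 31))
  X[, 1] <- y
  h <- holdout_evaluate(X, y, fraction = 2 / 3, seed = 8L, n_trees = 60L)
  expect_identical(h$n_train, 78L)
  expect_identical(h$n_test, 39L)
  expect_gt(h$accuracy, 0.9)
  h2 <- holdout_evaluate(X, y, fraction = 2 / 3, seed = 8L, n_trees = 60L)
  expect_identical(h, h2)
  expect_error(holdout_evaluate(X, y, fraction = 1.0), "empty")
})

test_that("the fitted model pipeline runs end to end on matrix features", {
  st <- small_study()
  mod <- suppressMessages(train_sc_model(
    st$matrix, st$phenotypes, tree = st$tree, feature_source = "matrix",
    mutagenesis_ids = st$causal_ids[1:2], n_perm = 49L, n_trees = 150L,
    seed = 2L))
  expect_s3_class(mod, "sc_model")
  expect_gte(sum(st$causal_ids %in% mod$features$family_id), 6L)
  expect_true(all(mod$training_scores >= 0 & mod$training_scores <= 1))
  expect_identical(mod$forest$feature_ids, mod$features$family_id)
  expect_output(print(mod), "structural-color classifier")
  # empty relabel list: round 2 is the round-1 model
  expect_identical(mod$forest, mod$forest_round1)
  # predicting on the training feature rows reproduces band logic
  pr <- predict(mod, unclass(mod$feature_table))
  expect_identical(pr$band, classify_score(pr$score, mod$bands))
})

test_that("operator relabels flip labels and retrain the second round", {
  st <- small_study()
  neg <- st$phenotypes$strain_id[st$phenotypes$label == "negative"][1:2]
  mod <- suppressMessages(train_sc_model(
    st$matrix, st$phenotypes, tree = NULL, feature_source = "matrix",
    relabel = neg, n_perm = 29L, n_trees = 100L, seed = 3L,
    statistic = "odds_ratio"))
  expect_identical(sort(mod$relabeled_strains), sort(neg))
  expect_identical(unname(mod$labels[match(neg, rownames(mod$feature_table))]),
                   c("positive", "positive"))
  expect_false(identical(mod$forest, mod$forest_round1))
  expect_warning(
    suppressMessages(train_sc_model(
      st$matrix, st$phenotypes, tree = NULL, feature_source = "matrix",
      relabel = "not-a-strain", n_perm = 29L, n_trees = 50L, seed = 3L,
      statistic = "odds_ratio")),
    "relabel ids")
})

test_that("HMM-backed scoring bands genomes and pools metagenomes", {
  st <- small_study()
  mod <- suppressMessages(train_sc_model(
    st$matrix, st$phenotypes, tree = NULL, msas = st$msas,
    proteomes = st$proteomes, feature_source = "hmm", n_perm = 29L,
    n_trees = 100L, seed = 4L, statistic = "odds_ratio"))
  pos_id <- st$phenotypes$strain_id[st$phenotypes$label == "positive"][1]
  neg_id <- st$phenotypes$strain_id[st$phenotypes$label == "negative"][1]
  sp <- score_genome(mod, st$proteomes[[pos_id]], subject_id = pos_id)
  sn <- score_genome(mod, st$proteomes[[neg_id]], subject_id = neg_id)
  expect_s3_class(sp, "sc_score")
  expect_gt(sp$score, sn$score)
  expect_identical(sp$band, classify_score(sp$score, mod$bands))
  expect_warning(s0 <- score_genome(mod, character(0)), "empty proteome")
  expect_identical(sum(s0$features), 0L)
  # pooling two proteomes ORs their feature vectors
  pooled <- score_metagenome(mod, c(st$proteomes[[pos_id]],
                                    st$proteomes[[neg_id]]))
  expect_identical(unname(pooled$features),
                   unname(pmax(sp$features, sn$features)))
  # a metagenome with the same vector as a genome scores identically
  expect_equal(pooled$score,
               predict_vote_fraction(mod$forest, pooled$features))
})
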