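# End-to-end structural-color classifier: pan-GWAS feature selection ->
# profile-HMM library -> presence/absence feature vectors -> random forest
# with a two-round relabeling step -> empirically derived score bands ->
# genome scoring and validation metrics.

#' Classification score bands
#'
#' Scores strictly above `upper` are likely SC-positive, strictly below
#' `lower` likely SC-negative, all others putatively positive. Equality
#' falls into the putative band.
#'
#' @param upper,lower band limits, `0 <= lower < upper <= 1`. Equal limits
#'   are accepted as the collapsed single-cut form (flagged with attribute
#'   `degenerate`), produced by [derive_score_bands()] on completely
#'   separated training scores.
#' @return object of class `sc_bands`.
#' @export
sc_bands <- function(upper = 0.68, lower = 0.39) {
  if (!(lower >= 0 && upper <= 1 && lower <= upper))
    stop("need 0 <= lower < upper <= 1")
  b <- structure(list(upper = upper, lower = lower), class = "sc_bands")
  if (lower == upper) attr(b, "degenerate") <- TRUE
  b
}

#' @export
print.sc_bands <- function(x, ...) {
  cat(sprintf("score bands: > %.3g likely positive, < %.3g likely negative%s\n",
              x$upper, x$lower,
              if (isTRUE(attr(x, "degenerate"))) " (degenerate single cut)" else ""))
  invisible(x)
}

#' Band assignment for a score
#'
#' @param score score(s) in \[0, 1\].
#' @param bands an [sc_bands()].
#' @return character vector over `likely_positive` / `putative` /
#'   `likely_negative`.
#' @export
classify_score <- function(score, bands) {
  ifelse(score > bands$upper, "likely_positive",
         ifelse(score < bands$lower, "likely_negative", "putative"))
}

#' Out-of-bag training scores of a forest
#'
#' Per training sample, the fraction of positive votes among the trees for
#' which the sample was out-of-bag — an unbiased training-set analogue of
#' the prediction-time vote fraction. Samples never out-of-bag fall back
#' to the full-forest vote fraction.
#'
#' @param forest an `sc_forest`.
#' @return named numeric vector of scores.
#' @export
training_scores <- function(forest) {
  tot <- rowSums(forest$oob_votes)
  s <- ifelse(tot > 0, forest$oob_votes[, 2] / pmax(tot, 1L), NA_real_)
  for (i in which(tot == 0))
    s[i] <- predict_vote_fraction(forest, forest$X[i, ])
  setNames(s, rownames(forest$X))
}

#' Flag labeled negatives with discordantly high scores
#'
#' Training strains labeled negative whose out-of-bag score strictly
#' exceeds `threshold` are returned for operator review (phenotype
#' re-testing); they are never relabeled automatically.
#'
#' @param forest an `sc_forest` trained on the strains.
#' @param labels per-strain labels aligned with the forest's training rows
#'   (`"positive"`/`"negative"` or 0/1).
#' @param threshold score cutoff.
#' @return character vector of flagged strain ids.
#' @export
flag_discordant_negatives <- function(forest, labels, threshold = 0.6) {
  y <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "positive" else as.logical(labels)
  s <- training_scores(forest)
  names(s)[!y & s > threshold]
}

#' Derive score bands from training scores
#'
#' `upper` is the maximum score among labeled-negative strains (above it,
#' every training strain is positive); `lower` is the minimum score among
#' gram-negative labeled-positive strains (below it, no gram-negative
#' training strain is positive). If the classes separate completely
#' (`upper < lower` in raw terms) the bands collapse to a single cut at
#' their midpoint, flagged with attribute `degenerate`.
#'
#' @param scores training scores.
#' @param labels aligned labels (`"positive"`/`"negative"` or 0/1).
#' @param gram_flags aligned gram status (`"negative"`/`"positive"`/
#'   `"unknown"`); when missing, all strains are treated as gram-negative
#'   with a warning.
#' @return an [sc_bands()].
#' @export
derive_score_bands <- function(scores, labels, gram_flags = NULL) {
  y <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "positive" else as.logical(labels)
  if (length(scores) != length(y)) stop("scores and labels must align")
  if (is.null(gram_flags) || all(gram_flags == "unknown")) {
    warning("no gram flags; treating all strains as gram-negative")
    gram_flags <- rep("negative", length(y))
  }
  if (!any(!y)) stop("no labeled-negative strains; bands undefined")
  gneg_pos <- y & gram_flags == "negative"
  if (!any(gneg_pos)) stop("no gram-negative positive strains; bands undefined")
  upper <- max(scores[!y])
  lower <- min(scores[gneg_pos])
  if (lower >= upper) {
    cut <- (upper + lower) / 2
    b <- structure(list(upper = cut, lower = cut), class = "sc_bands")
    attr(b, "degenerate") <- TRUE
    return(b)
  }
  sc_bands(upper = upper, lower = lower)
}

#' Train the structural-color classifier
#'
#' Runs the full modelling pipeline: association testing and feature
#' selection ([run_pangwas()], [select_sc_features()]), profile-HMM
#' library construction from the selected families' alignments, binary
#' feature extraction for every training strain, a first random forest,
#' flagging of discordant negatives, application of operator-confirmed
#' relabels, a second forest, and score-band derivation from the final
#' out-of-bag training scores.
#'
#' @param matrix an [ortholog_matrix()].
#' @param phenotypes a [phenotype_table()] (unknown labels are dropped).
#' @param tree optional rooted `phylo` for the tree-aware tests.
#' @param msas named list of per-family alignments (needed for
#'   `feature_source = "hmm"`).
#' @param proteomes named list of per-strain protein sets (needed for
#'   `feature_source = "hmm"`).
#' @param mutagenesis_ids families with experimental knockout evidence.
#' @param relabel strain ids confirmed positive after re-testing; applied
#'   before the second forest round.
#' @param feature_source `"hmm"` (profile-HMM presence calls, the native
#'   pipeline) or `"matrix"` (use the ortholog matrix columns directly).
#' @param alpha feature-selection significance level.
#' @param n_perm permutations per family in the association stage.
#' @param n_trees,mtry forest size parameters.
#' @param seed RNG seed for the stochastic stages.
#' @param flag_threshold cutoff for [flag_discordant_negatives()].
#' @param statistic permutation statistic, see [permutation_pvalue()].
#' @return object of class `sc_model`.
#' @export
train_sc_model <- function(matrix, phenotypes, tree = NULL, msas = NULL,
                           proteomes = NULL, mutagenesis_ids = character(),
                           relabel = character(),
                           feature_source = c("hmm", "matrix"),
                           alpha = 0.05, n_perm = 199L, n_trees = 500L,
                           mtry = NULL, seed = 1L, flag_threshold = 0.6,
                           statistic = c("pairs", "odds_ratio")) {
  feature_source <- match.arg(feature_source)
  al <- align_matrix_phenotypes(matrix, phenotypes)
  m <- al$matrix; ph <- al$phenotypes

  gwas <- run_pangwas(m, ph, tree = tree, n_perm = n_perm, seed = seed,
                      statistic = statistic)
  sel <- select_sc_features(gwas, alpha = alpha,
                            mutagenesis_ids = mutagenesis_ids)
  missing_sel <- setdiff(sel$family_id, colnames(m))
  if (length(missing_sel)) {
    warning("selected families absent from the matrix dropped: ",
            paste(utils::head(missing_sel, 5), collapse = ", "))
    sel <- sel[sel$family_id %in% colnames(m), , drop = FALSE]
  }
  if (nrow(sel) < 2L) stop("feature selection returned < 2 families")

  if (feature_source == "hmm") {
    if (is.null(msas) || is.null(proteomes))
      stop("feature_source = 'hmm' needs msas and proteomes")
    lib <- build_hmm_library(msas[intersect(sel$family_id, names(msas))])
    if (length(lib) < 2L) stop("HMM library has < 2 usable families")
    features <- build_feature_table(lib, proteomes[rownames(m)])
    sel <- sel[sel$family_id %in% names(lib), , drop = FALSE]
  } else {
    lib <- NULL
    features <- feature_table(m[, sel$family_id, drop = FALSE])
  }

  labels1 <- ph$label
  forest1 <- train_forest(features, labels1, n_trees = n_trees, mtry = mtry,
                          seed = seed)
  flagged <- flag_discordant_negatives(forest1, labels1,
                                       threshold = flag_threshold)

  labels2 <- labels1
  unknown_relabel <- setdiff(relabel, rownames(features))
  if (length(unknown_relabel))
    warning("relabel ids not in the training set: ",
            paste(unknown_relabel, collapse = ", "))
  labels2[rownames(features) %in% relabel] <- "positive"
  forest2 <- if (length(intersect(relabel, rownames(features)))) {
    train_forest(features, labels2, n_trees = n_trees, mtry = mtry,
                 seed = seed)
  } else forest1

  scores2 <- training_scores(forest2)
  bands <- derive_score_bands(scores2, labels2, gram_flags = ph$gram)

  structure(list(
    features = sel, hmm_library = lib, forest = forest2,
    forest_round1 = forest1, bands = bands,
    relabeled_strains = intersect(relabel, rownames(features)),
    flagged_negatives = flagged, gwas = gwas,
    feature_table = features, labels = labels2, labels_initial = labels1,
    phenotypes = ph, training_scores = scores2,
    feature_source = feature_source,
    config = list(alpha = alpha, n_perm = n_perm, n_trees = n_trees,
                  mtry = forest2$mtry, seed = seed,
                  flag_threshold = flag_threshold)
  ), class = "sc_model")
}

#' @export
print.sc_model <- function(x, ...) {
  cat("structural-color classifier\n")
  cat(sprintf("  features: %d selected families (%s)\n", nrow(x$features),
              x$feature_source))
  cat(sprintf("  forest: %d trees, OOB error %.3f (round 1: %.3f)\n",
              x$forest$n_trees, x$forest$oob_err, x$forest_round1$oob_err))
  cat(sprintf("  bands: > %.3g likely positive, < %.3g likely negative\n",
              x$bands$upper, x$bands$lower))
  if (length(x$relabeled_strains))
    cat(sprintf("  relabeled strains: %s\n",
                paste(x$relabeled_strains, collapse = ", ")))
  invisible(x)
}

#' @export
summary.sc_model <- function(object, ...) {
  cat("feature evidence:\n")
  print(colSums(object$features[, c("fisher", "permutation", "pairwise",
                                    "mutagenesis")]))
  cat(sprintf("\ntraining strains: %d (%d positive after relabeling)\n",
              length(object$labels), sum(object$labels == "positive")))
  cat(sprintf("flagged discordant negatives: %s\n",
              if (length(object$flagged_negatives))
                paste(object$flagged_negatives, collapse = ", ") else "none"))
  print(object)
  invisible(object)
}

#' Score one genome
#'
#' Extracts the binary profile-HMM feature vector of the proteome and
#' returns its forest vote fraction with the band assignment.
#'
#' @param model an `sc_model` trained with `feature_source = "hmm"`.
#' @param proteome named character vector of protein sequences; an empty
#'   proteome is scored on the all-zero vector with a warning.
#' @param subject_id identifier attached to the result.
#' @return object of class `sc_score`: `subject_id`, `score`, `band` and
#'   the feature vector.
#' @export
score_genome <- function(model, proteome, subject_id = NA_character_) {
  if (is.null(model$hmm_library))
    stop("model was trained on matrix features; score feature vectors via predict()")
  fv <- if (length(proteome) == 0L) {
    warning("empty proteome; scoring the all-zero feature vector")
    setNames(integer(length(model$hmm_library)), names(model$hmm_library))
  } else genome_feature_vector(model$hmm_library, proteome)
  s <- predict_vote_fraction(model$forest, fv)
  structure(list(subject_id = subject_id, score = s,
                 band = classify_score(s, model$bands), features = fv),
            class = "sc_score")
}

#' @export
print.sc_score <- function(x, ...) {
  cat(sprintf("SC score%s: %.3f (%s)\n",
              if (!is.na(x$subject_id)) paste0(" for ", x$subject_id) else "",
              x$score, x$band))
  invisible(x)
}

#' @export
#' @rdname score_genome
#' @param object an `sc_model`.
#' @param newdata a proteome (character vector of sequences), a named list
#'   of proteomes, or a binary feature matrix/vector in model feature
#'   order.
#' @param ... unused.
predict.sc_model <- function(object, newdata, ...) {
  if (is.character(newdata))
    return(score_genome(object, newdata))
  if (is.list(newdata)) {
    out <- lapply(names(newdata), function(id)
      score_genome(object, newdata[[id]], subject_id = id))
    return(data.frame(subject_id = names(newdata),
                      score = vapply(out, `[[`, 0, "score"),
                      band = vapply(out, `[[`, "", "band"),
                      stringsAsFactors = FALSE))
  }
  s <- predict_vote_fraction(object$forest, newdata)
  data.frame(subject_id = if (is.matrix(newdata) && !is.null(rownames(newdata)))
    rownames(newdata) else seq_along(s),
    score = s, band = classify_score(s, object$bands),
    stringsAsFactors = FALSE)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: concordant (positive scored above negative)
#' pairs count 1, tied-score pairs 0.5, divided by `n_pos * n_neg`.
#'
#' @param scores numeric scores.
#' @param labels binary labels (`"positive"`/`"negative"`, 0/1 or
#'   logical); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "positive" else as.logical(labels)
  keep <- !is.na(y) & !is.na(scores)
  y <- y[keep]; scores <- scores[keep]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified holdout evaluation
#'
#' Splits the samples into a training fraction and a test remainder,
#' stratified by class, trains a forest on the training side and reports
#' held-out accuracy. If a class is missing from either side the split is
#' redrawn (up to 100 attempts, with a warning).
#'
#' @param features binary feature matrix.
#' @param labels binary labels.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @param n_trees,mtry forest parameters.
#' @return list with `accuracy`, `auc`, `n_train`, `n_test`.
#' @export
holdout_evaluate <- function(features, labels, fraction = 2 / 3, seed = 1L,
                             n_trees = 500L, mtry = NULL) {
  X <- unclass(as.matrix(features))
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "positive")
  else as.integer(as.logical(labels))
  n <- nrow(X)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n_train <- floor(fraction * n)
  if (n_train < 2L || n_train >= n)
    stop("fraction leaves an empty train or test side")
  set.seed(as.integer(seed))
  draw_split <- function() {
    # stratified: per-class allocation by largest remainder to hit n_train
    idx_by_class <- split(seq_len(n), y)
    quota <- vapply(idx_by_class, length, 0L) * fraction
    base <- floor(quota)
    rem <- n_train - sum(base)
    if (rem > 0) {
      add <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1L
    }
    unlist(mapply(function(ix, k) sample(ix, min(k, length(ix))),
                  idx_by_class, base, SIMPLIFY = FALSE), use.names = FALSE)
  }
  for (attempt in seq_len(100L)) {
    train <- sort(draw_split())
    test <- setdiff(seq_len(n), train)
    if (length(unique(y[train])) == 2L && length(unique(y[test])) == 2L)
      break
    if (attempt == 100L) stop("could not obtain a split with both classes")
    warning("degenerate split; resampling")
  }
  fit <- train_forest(X[train, , drop = FALSE], y[train], n_trees = n_trees,
                      mtry = mtry, seed = as.integer(seed))
  s <- predict_vote_fraction(fit, X[test, , drop = FALSE])
  pred <- as.integer(s > 0.5)
  list(accuracy = mean(pred == y[test]),
       auc = roc_auc(s, y[test]),
       n_train = length(train), n_test = length(test))
}

#' The printed validation-strain table
#'
#' The validation collection shipped with the package: 100 cultivated
#' strains with their classifier scores, observed SC phenotype (Y/N or
#' blank for untested), taxonomy and gram status. Used to validate the
#' classifier's discrimination (AUC) against wet-lab phenotype calls.
#'
#' @return data.frame with columns `species`, `habitat`, `score`, `sc`,
#'   `source`, `class`, `phylum`, `gram` and a derived `label`
#'   (`positive`/`negative`/`unknown`).
#' @export
validation_strains <- function() {
  path <- system.file("extdata", "validation_strains.csv",
                      package = "iridetect", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$label <- ifelse(d$sc == "Y", "positive",
                    ifelse(d$sc == "N", "negative", "unknown"))
  d
}

#' Plot the training-score distribution of a fitted classifier
#'
#' Histogram of the out-of-bag training scores, colored by label, with
#' the derived band limits drawn as vertical lines.
#'
#' @param x an `sc_model`.
#' @param breaks histogram breaks passed to [graphics::hist()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.sc_model <- function(x, breaks = seq(0, 1, by = 0.05), ...) {
  s <- x$training_scores
  pos <- x$labels == "positive"
  hp <- graphics::hist(s[pos], breaks = breaks, plot = FALSE)
  hn <- graphics::hist(s[!pos], breaks = breaks, plot = FALSE)
  ylim <- c(0, max(hp$counts, hn$counts))
  graphics::plot(hp, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlim = c(0, 1), ylim = ylim, xlab = "SC score (OOB)",
                 main = "training scores", ...)
  graphics::plot(hn, col = grDevices::adjustcolor("grey40", 0.6),
                 add = TRUE)
  graphics::abline(v = c(x$bands$lower, x$bands$upper), lty = 2,
                   col = "red3")
  graphics::legend("top", fill = c("steelblue", "grey40"),
                   legend = c("positive", "negative"), bty = "n")
  invisible(x)
}
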