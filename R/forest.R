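# From-scratch random-forest classifier over binary feature vectors, with
# out-of-bag (OOB) bookkeeping, per-sample vote fractions and Gini
# importances.  Defaults follow the conventional classification forest:
# n_trees = 500, mtry = floor(sqrt(p)), bootstrap sampling with replacement,
# trees grown unpruned to purity.

.gini <- function(n0, n1) {
  n <- n0 + n1
  ifelse(n == 0, 0, 1 - ((n0 / n)^2 + (n1 / n)^2))
}

# Grow one tree on a bootstrap sample.  Returns flat parallel vectors:
# feature (NA at leaves), left/right child ids, class counts, prediction.
.grow_tree <- function(X, y, idx, mtry, prevalent) {
  p <- ncol(X)
  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$left <- integer(0); env$right <- integer(0)
  env$n0 <- integer(0); env$n1 <- integer(0); env$pred <- integer(0)
  env$imp <- numeric(p)
  n_root <- length(idx)
  new_node <- function() {
    i <- length(env$feature) + 1L
    env$feature[i] <- NA_integer_; env$left[i] <- 0L; env$right[i] <- 0L
    env$n0[i] <- 0L; env$n1[i] <- 0L; env$pred[i] <- 0L
    i
  }
  grow <- function(idx) {
    me <- new_node()
    yv <- y[idx]
    nv <- length(idx); n1v <- sum(yv); n0v <- nv - n1v
    env$n0[me] <- n0v; env$n1[me] <- n1v
    env$pred[me] <- if (n1v > n0v) 1L else if (n0v > n1v) 0L else prevalent
    if (n0v == 0L || n1v == 0L) return(me)
    cand <- sort(sample.int(p, min(mtry, p)))
    xm <- X[idx, cand, drop = FALSE]
    sR <- colSums(xm); s1R <- colSums(xm * yv)
    nL <- nv - sR; n1L <- n1v - s1R
    gP <- .gini(n0v, n1v)
    dec <- gP - (nL * .gini(nL - n1L, n1L) + sR * .gini(sR - s1R, s1R)) / nv
    dec[nL == 0L | sR == 0L] <- -Inf
    best <- max(dec)
    if (!is.finite(best) || best <= 1e-12) return(me)
    f <- cand[which(dec >= best - 1e-12)[1]]   # tie: lowest feature index
    env$feature[me] <- f
    env$imp[f] <- env$imp[f] + (nv / n_root) * best
    xcol <- X[idx, f]
    env$left[me] <- grow(idx[xcol == 0L])
    env$right[me] <- grow(idx[xcol == 1L])
    me
  }
  grow(idx)
  list(feature = env$feature, left = env$left, right = env$right,
       n0 = env$n0, n1 = env$n1, pred = env$pred, imp = env$imp)
}

.tree_predict <- function(tree, x) {
  i <- 1L
  while (!is.na(tree$feature[i]))
    i <- if (x[tree$feature[i]] == 0L) tree$left[i] else tree$right[i]
  tree$pred[i]
}

#' Train a random forest on binary features
#'
#' Each tree is grown on a bootstrap sample of size n; at every node `mtry`
#' features are drawn without replacement and the split with the largest
#' Gini impurity decrease is taken (ties broken toward the lowest feature
#' index), recursing until node purity or exhaustion of informative splits.
#' Out-of-bag votes, the OOB error and per-feature Gini importances are
#' recorded. Fully deterministic under a fixed seed.
#'
#' @param features [feature_table()] or binary matrix, samples in rows.
#' @param labels per-sample class: `"positive"`/`"negative"`, 0/1 or
#'   logical; both classes must be present.
#' @param n_trees number of trees.
#' @param mtry features tried per split, default `floor(sqrt(p))`.
#' @param seed RNG seed.
#' @return an object of class `sc_forest`.
#' @export
train_forest <- function(features, labels, n_trees = 500L, mtry = NULL,
                         seed = 1L) {
  X <- unclass(as.matrix(features))
  storage.mode(X) <- "integer"
  if (!all(X %in% c(0L, 1L))) stop("features must be binary")
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "positive")
  else as.integer(as.logical(labels))
  if (length(y) != nrow(X)) stop("label length does not match feature rows")
  if (anyNA(y)) stop("labels must be binary")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  prevalent <- if (sum(y) >= n - sum(y)) 1L else 0L
  set.seed(as.integer(seed))
  trees <- vector("list", n_trees)
  oob_sets <- vector("list", n_trees)
  oob_votes <- matrix(0L, n, 2L)
  imp <- numeric(p)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- which(tabulate(boot, n) == 0L)
    tr <- .grow_tree(X, y, boot, mtry, prevalent)
    imp <- imp + tr$imp
    tr$imp <- NULL
    trees[[b]] <- tr
    oob_sets[[b]] <- oob
    for (i in oob) {
      cl <- .tree_predict(tr, X[i, ])
      oob_votes[i, cl + 1L] <- oob_votes[i, cl + 1L] + 1L
    }
  }
  covered <- rowSums(oob_votes) > 0L
  oob_pred <- ifelse(oob_votes[, 2] > oob_votes[, 1], 1L,
                     ifelse(oob_votes[, 1] > oob_votes[, 2], 0L, prevalent))
  oob_err <- mean(oob_pred[covered] != y[covered])
  if (any(!covered))
    message("train_forest: ", sum(!covered),
            " sample(s) never out-of-bag; excluded from OOB error")
  structure(list(
    trees = trees, n_trees = n_trees, mtry = mtry, seed = as.integer(seed),
    feature_ids = colnames(X), n_features = p, X = X, y = y,
    prevalent = prevalent,
    oob_sets = oob_sets, oob_votes = oob_votes, oob_err = oob_err,
    n_oob_excluded = sum(!covered),
    importance = setNames(imp / n_trees, colnames(X))
  ), class = "sc_forest")
}

#' @export
print.sc_forest <- function(x, ...) {
  cat(sprintf("random forest: %d trees, mtry %d, %d samples x %d features\n",
              x$n_trees, x$mtry, nrow(x$X), ncol(x$X)))
  cat(sprintf("  OOB error: %.4f\n", x$oob_err))
  invisible(x)
}

#' Vote fraction for feature vectors
#'
#' The fraction of trees whose leaf classifies the input as the positive
#' class; this fraction is the SC score of a genome.
#'
#' @param model an `sc_forest`.
#' @param feature_vector binary vector in the model's feature order, or a
#'   matrix of such rows.
#' @return numeric vote fraction(s) in \[0, 1\].
#' @export
predict_vote_fraction <- function(model, feature_vector) {
  if (is.matrix(feature_vector)) {
    return(vapply(seq_len(nrow(feature_vector)), function(i)
      predict_vote_fraction(model, feature_vector[i, ]), 0))
  }
  if (length(feature_vector) != model$n_features)
    stop("feature vector length does not match the model")
  x <- as.integer(feature_vector)
  votes <- vapply(model$trees, .tree_predict, 0L, x = x)
  mean(votes == 1L)
}

#' @export
#' @rdname predict_vote_fraction
#' @param object an `sc_forest`.
#' @param newdata feature matrix or vector.
#' @param type `"score"` for vote fractions, `"class"` for 0/1 calls at 0.5.
#' @param ... unused.
predict.sc_forest <- function(object, newdata, type = c("score", "class"),
                              ...) {
  type <- match.arg(type)
  s <- predict_vote_fraction(object, newdata)
  if (type == "class") as.integer(s > 0.5) else s
}

#' Out-of-bag error of a trained forest
#'
#' Fraction of training samples misclassified by the majority vote of the
#' trees for which they were out-of-bag. Samples never out-of-bag are
#' excluded (their count is stored as `n_oob_excluded`).
#'
#' @param model an `sc_forest`.
#' @param recompute recount from the stored per-tree OOB index sets instead
#'   of returning the stored value.
#' @return error rate in \[0, 1\].
#' @export
oob_error <- function(model, recompute = FALSE) {
  if (!recompute) return(model$oob_err)
  n <- nrow(model$X)
  votes <- matrix(0L, n, 2L)
  for (b in seq_along(model$trees)) {
    for (i in model$oob_sets[[b]]) {
      cl <- .tree_predict(model$trees[[b]], model$X[i, ])
      votes[i, cl + 1L] <- votes[i, cl + 1L] + 1L
    }
  }
  covered <- rowSums(votes) > 0L
  pred <- ifelse(votes[, 2] > votes[, 1], 1L,
                 ifelse(votes[, 1] > votes[, 2], 0L, model$prevalent))
  mean(pred[covered] != model$y[covered])
}

#' Gini importances of a trained forest
#'
#' Mean (over trees) total Gini impurity decrease attributed to each
#' feature; features never split on score 0.
#'
#' @param model an `sc_forest`.
#' @return named numeric vector, one entry per feature.
#' @export
gini_importances <- function(model) model$importance

#' Serialize a forest to JSON and back
#'
#' The layout stores per tree the parallel node vectors (split feature
#' index, children, class counts, leaf prediction) plus the model
#' metadata, so trained models are portable as plain text.
#'
#' @param model an `sc_forest`.
#' @param path file path.
#' @export
write_forest_json <- function(model, path) {
  payload <- list(
    n_trees = model$n_trees, mtry = model$mtry, seed = model$seed,
    feature_ids = model$feature_ids, n_features = model$n_features,
    prevalent = model$prevalent,
    oob_err = model$oob_err, importance = as.list(model$importance),
    trees = lapply(model$trees, function(tr)
      lapply(tr, function(v) ifelse(is.na(v), -1L, as.integer(v))))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest_json
#' @return `read_forest_json` returns an `sc_forest` usable for prediction
#'   (training data and OOB bookkeeping are not serialized).
#' @export
read_forest_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  trees <- lapply(payload$trees, function(raw) {
    tr <- lapply(raw, function(v) as.integer(unlist(v)))
    tr$feature[tr$feature < 0L] <- NA_integer_
    tr
  })
  payload[c("feature_ids", "importance")] <-
    lapply(payload[c("feature_ids", "importance")], unlist)
  structure(list(
    trees = trees, n_trees = payload$n_trees, mtry = payload$mtry,
    seed = payload$seed, feature_ids = payload$feature_ids,
    n_features = payload$n_features,
    prevalent = payload$prevalent, oob_err = payload$oob_err,
    importance = unlist(payload$importance)
  ), class = "sc_forest")
}
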