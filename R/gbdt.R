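# Gradient-boosted regression trees for binary candidate classification,
# built from first principles on the logistic deviance: F0 is the prior
# log-odds, each round fits a CART to the negative gradient (residual
# y - sigmoid(F)) and replaces leaf means with a one-step Newton value,
# shrunk by the learning rate.

#' Initial log-odds of a training set
#'
#' `log(p / (1 - p))` for the positive-class proportion p. Both classes
#' must be present.
#'
#' @param labels 0/1 vector.
#' @return scalar log-odds.
#' @export
gbdtInitF0 <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  p <- mean(labels)
  if (p <= 0 || p >= 1)
    stop("training labels must contain both classes", call. = FALSE)
  log(p / (1 - p))
}

#' Negative gradient of the logistic loss
#'
#' The working residual of each boosting round:
#' `r_i = y_i - 1 / (1 + exp(-F_i))`.
#'
#' @param labels 0/1 vector.
#' @param scores current log-odds scores F.
#' @return numeric vector of residuals.
#' @export
negativeGradient <- function(labels, scores) {
  labels - stats::plogis(scores)
}

# Trees are flat node tables: feature (0 = leaf), threshold, left/right
# child row indices, value (leaf prediction), n (samples routed here).

.best_split <- function(X, target, min_leaf) {
  n <- length(target)
  best <- NULL
  total <- sum(target)
  totalsq <- sum(target^2)
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    ord <- order(x)
    xs <- x[ord]
    ts <- target[ord]
    csum <- cumsum(ts)
    # candidate split after position i: left = 1..i
    i <- seq_len(n - 1L)
    valid <- which(xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf)
    if (!length(valid)) next
    nl <- valid
    nr <- n - nl
    sl <- csum[valid]
    sr <- total - sl
    # SSE reduction = sl^2/nl + sr^2/nr - total^2/n (constant term dropped)
    gain <- sl^2 / nl + sr^2 / nr
    bi <- which.max(gain)
    g <- gain[bi]
    if (is.null(best) || g > best$gain + 1e-12) {
      pos <- valid[bi]
      best <- list(gain = g, feature = f,
                   threshold = (xs[pos] + xs[pos + 1L]) / 2)
    }
  }
  best
}

#' Fit a CART regression tree
#'
#' Greedy binary splitting that minimizes the squared error of the targets,
#' with an exhaustive search over features and midpoints of consecutive
#' distinct sorted values. Ties are broken toward the lowest feature index,
#' then the lowest threshold. Degenerate data yield a single leaf holding
#' the target mean.
#'
#' @param X numeric feature matrix.
#' @param target numeric response (boosting residuals).
#' @param maxDepth depth limit (0 = a single leaf).
#' @param minLeaf minimum samples in each child.
#' @return a tree: data.frame with columns `feature` (0 for leaves),
#'   `threshold`, `left`, `right`, `value`, `n`; samples with
#'   `x[feature] <= threshold` go left. Carries attribute `leaf_of`:
#'   the leaf row index of every training sample.
#' @export
fitCart <- function(X, target, maxDepth = 3L, minLeaf = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  nodes <- data.frame(feature = integer(0), threshold = numeric(0),
                      left = integer(0), right = integer(0),
                      value = numeric(0), n = integer(0))
  leaf_of <- integer(n)
  new_node <- function() {
    nodes[nrow(nodes) + 1L, ] <<- list(0L, NA_real_, 0L, 0L, NA_real_, 0L)
    nrow(nodes)
  }
  grow <- function(id, idx, depth) {
    nodes$n[id] <<- length(idx)
    nodes$value[id] <<- mean(target[idx])
    if (depth >= maxDepth || length(idx) < max(2L * minLeaf, 2L) ||
        stats::var(target[idx]) == 0) {
      leaf_of[idx] <<- id
      return(invisible(NULL))
    }
    sp <- .best_split(X[idx, , drop = FALSE], target[idx], minLeaf)
    if (is.null(sp)) {
      leaf_of[idx] <<- id
      return(invisible(NULL))
    }
    goleft <- X[idx, sp$feature] <= sp$threshold
    nodes$feature[id] <<- sp$feature
    nodes$threshold[id] <<- sp$threshold
    lid <- new_node(); nodes$left[id] <<- lid
    rid <- new_node(); nodes$right[id] <<- rid
    grow(lid, idx[goleft], depth + 1L)
    grow(rid, idx[!goleft], depth + 1L)
  }
  root <- new_node()
  grow(root, seq_len(n), 0L)
  attr(nodes, "leaf_of") <- leaf_of
  nodes
}

#' Route samples through a tree
#'
#' @param tree node table from [fitCart()].
#' @param X feature matrix.
#' @return integer vector of leaf row indices, one per sample.
#' @export
treeLeafIndex <- function(tree, X) {
  X <- as.matrix(X)
  vapply(seq_len(nrow(X)), function(i) {
    id <- 1L
    while (tree$feature[id] > 0L) {
      id <- if (X[i, tree$feature[id]] <= tree$threshold[id])
        tree$left[id] else tree$right[id]
    }
    id
  }, integer(1))
}

#' Newton leaf values for the logistic loss
#'
#' Replaces each leaf's mean with the one-step Newton value
#' `sum(r_i) / sum((y_i - r_i) (1 - y_i + r_i))` over the samples routed to
#' that leaf; the denominator, `sum(p (1 - p))` in terms of the predicted
#' probabilities, is floored at 1e-12 so pure leaves stay finite.
#'
#' @param tree node table from [fitCart()] (with its `leaf_of` attribute,
#'   or supply `leafIndex`).
#' @param labels 0/1 training labels.
#' @param residuals negative-gradient targets the tree was fitted to.
#' @param leafIndex optional integer vector routing each sample to a leaf.
#' @return the tree with leaf `value`s replaced.
#' @export
leafValues <- function(tree, labels, residuals, leafIndex = NULL) {
  if (is.null(leafIndex)) leafIndex <- attr(tree, "leaf_of")
  for (id in unique(leafIndex)) {
    in_leaf <- leafIndex == id
    num <- sum(residuals[in_leaf])
    den <- sum((labels[in_leaf] - residuals[in_leaf]) *
               (1 - labels[in_leaf] + residuals[in_leaf]))
    tree$value[id] <- num / max(den, 1e-12)
  }
  tree
}

#' Fit the gradient-boosted tree classifier
#'
#' Runs `nTrees` boosting rounds: compute residuals, fit a CART to them,
#' replace leaf means by Newton values, and add the shrunken leaf
#' contributions to the score. The training log-loss after every round is
#' recorded in the model.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param labels 0/1 vector.
#' @param nTrees boosting rounds (default 80).
#' @param learningRate shrinkage (default 0.03).
#' @param maxDepth,minLeaf CART controls.
#' @return a [GBDTModel-class] object.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 100, 2)
#' y <- as.numeric(X[, 1] + X[, 2] > 0)
#' m <- gbdtFit(X, y, nTrees = 20)
#' mean((gbdtPredict(m, X) > 0.5) == y)
#' @export
gbdtFit <- function(X, labels, nTrees = 80L, learningRate = 0.03,
                    maxDepth = 3L, minLeaf = 5L) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels))
    stop("feature matrix and labels disagree in length", call. = FALSE)
  f0 <- gbdtInitF0(labels)
  scores <- rep(f0, nrow(X))
  trees <- vector("list", nTrees)
  loss <- numeric(nTrees)
  for (m in seq_len(nTrees)) {
    r <- negativeGradient(labels, scores)
    tree <- fitCart(X, r, maxDepth, minLeaf)
    leafIndex <- attr(tree, "leaf_of")
    tree <- leafValues(tree, labels, r, leafIndex)
    scores <- scores + learningRate * tree$value[leafIndex]
    attr(tree, "leaf_of") <- NULL
    trees[[m]] <- tree
    p <- stats::plogis(scores)
    loss[m] <- -mean(labels * log(pmax(p, 1e-15)) +
                     (1 - labels) * log(pmax(1 - p, 1e-15)))
  }
  new("GBDTModel", f0 = f0, trees = trees, learningRate = learningRate,
      nTrees = as.integer(nTrees),
      featureNames = colnames(X) %||% character(0), trainLoss = loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities
#'
#' Accumulates the initial log-odds and every tree's shrunken leaf value,
#' then applies the logistic function.
#'
#' @param model a [GBDTModel-class].
#' @param X feature matrix with the training columns.
#' @return probabilities in (0, 1), one per row of `X`.
#' @export
gbdtPredict <- function(model, X) {
  X <- as.matrix(X)
  if (length(model@featureNames) && !is.null(colnames(X))) {
    if (!all(model@featureNames %in% colnames(X)))
      stop("feature columns do not match the trained model", call. = FALSE)
    X <- X[, model@featureNames, drop = FALSE]
  } else if (length(model@featureNames) &&
             ncol(X) != length(model@featureNames)) {
    stop("feature dimension does not match the trained model", call. = FALSE)
  }
  scores <- rep(model@f0, nrow(X))
  for (tree in model@trees)
    scores <- scores + model@learningRate * tree$value[treeLeafIndex(tree, X)]
  stats::plogis(scores)
}

#' Serialize / load a fitted model as JSON
#'
#' The schema (versioned `"rgdetect-gbdt-1"`) stores `f0`, the learning
#' rate, feature names, and each tree as parallel node arrays. Loading a
#' file with a different schema version fails.
#'
#' @param model a [GBDTModel-class].
#' @param path file path.
#' @return `readGbdtModel`: the restored [GBDTModel-class].
#' @export
writeGbdtModel <- function(model, path) {
  obj <- list(schema = "rgdetect-gbdt-1",
              f0 = model@f0, learning_rate = model@learningRate,
              feature_names = model@featureNames,
              train_loss = model@trainLoss,
              trees = lapply(model@trees, function(t)
                list(feature = t$feature, threshold = t$threshold,
                     left = t$left, right = t$right, value = t$value,
                     n = t$n)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeGbdtModel
#' @export
readGbdtModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "rgdetect-gbdt-1"))
    stop("unsupported model schema: ", obj$schema, call. = FALSE)
  trees <- lapply(seq_len(if (is.data.frame(obj$trees)) nrow(obj$trees)
                          else length(obj$trees)), function(i) {
    t <- if (is.data.frame(obj$trees)) lapply(obj$trees, `[[`, i)
         else obj$trees[[i]]
    data.frame(feature = as.integer(t$feature),
               threshold = as.numeric(t$threshold),
               left = as.integer(t$left), right = as.integer(t$right),
               value = as.numeric(t$value), n = as.integer(t$n))
  })
  new("GBDTModel", f0 = obj$f0, trees = trees,
      learningRate = obj$learning_rate,
      nTrees = length(trees),
      featureNames = as.character(obj$feature_names %||% character(0)),
      trainLoss = as.numeric(obj$train_loss %||% numeric(0)))
}
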