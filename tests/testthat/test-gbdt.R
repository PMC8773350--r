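test_that("initial log-odds and the negative gradient follow the closed forms", {
  expect_equal(gbdtInitF0(c(0, 0, 1, 1)), 0)
  expect_equal(gbdtInitF0(c(rep(1, 9), 0)), log(9))
  expect_error(gbdtInitF0(c(1, 1, 1)), "both classes")
  expect_error(gbdtInitF0(c(0, 2)), "0/1")

  expect_equal(negativeGradient(1, 0), 0.5)
  expect_equal(negativeGradient(0, 0), -0.5)
  expect_equal(negativeGradient(1, 50), 0, tolerance = 1e-9)
  expect_equal(negativeGradient(c(1, 0), c(1, -1)),
               c(1 - plogis(1), -plogis(-1)))
})

test_that("regression trees split separable data and match the exhaustive SSE oracle", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  tree <- fitCart(X, c(-1, -1, 1, 1), maxDepth = 1L, minLeaf = 1L)
  expect_equal(tree$feature[1], 1L)
  expect_gt(tree$threshold[1], 1)
  expect_lt(tree$threshold[1], 10)
  expect_equal(sort(tree$value[tree$feature == 0]), c(-1, 1))

  # constant targets: a single leaf
  t2 <- fitCart(X, rep(3, 4), maxDepth = 3L, minLeaf = 1L)
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$value, 3)

  # depth-2 trees: split SSE matches brute-force enumeration of all splits
  sse_of_split <- function(x, y, thr) {
    l <- y[x <= thr]; r <- y[x > thr]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(runif(40), 20, 2)
    y <- rnorm(20)
    tree <- fitCart(X, y, maxDepth = 1L, minLeaf = 1L)
    got <- sse_of_split(X[, tree$feature[1]], y, tree$threshold[1])
    best <- Inf
    for (f in 1:2) for (thr in sort(unique(X[, f]))[-20])
      best <- min(best, sse_of_split(X[, f], y, thr))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("leaf values implement the one-step Newton formula", {
  X <- matrix(c(0, 10), 2, 1)
  y <- c(1, 0)
  r <- c(0.5, -0.5)
  tree <- fitCart(X, r, maxDepth = 1L, minLeaf = 1L)
  tree <- leafValues(tree, y, r)
  leaves <- tree[tree$feature == 0, ]
  # single-sample leaves: 0.5 / ((1-0.5)(1-1+0.5)) = 2, mirrored for y=0
  expect_equal(sort(leaves$value), c(-2, 2))

  # multi-sample leaf equals direct summation
  y2 <- c(1, 1, 0, 1)
  r2 <- c(0.3, 0.4, -0.2, 0.1)
  t2 <- fitCart(matrix(1, 4, 1), r2, maxDepth = 0L, minLeaf = 1L)
  t2 <- leafValues(t2, y2, r2)
  expect_equal(t2$value[1],
               sum(r2) / sum((y2 - r2) * (1 - y2 + r2)))
})

test_that("the first boosting iteration reproduces the hand computation", {
  # 4 samples, 1 feature, balanced labels, epsilon = 0.03, depth 1
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  y <- c(0, 0, 1, 1)
  model <- gbdtFit(X, y, nTrees = 1L, learningRate = 0.03,
                   maxDepth = 1L, minLeaf = 1L)
  # F0 = log(0.5/0.5) = 0; residuals r = y - 0.5 = (-.5,-.5,.5,.5)
  expect_equal(model@f0, 0)
  tree <- model@trees[[1]]
  # each leaf: sum r = +-1, sum (y-r)(1-y+r) = 2 * 0.25 -> c = +-2
  expect_equal(sort(tree$value[tree$feature == 0]), c(-2, 2))
  # F1 = 0 +- 0.03 * 2 -> p = plogis(+-0.06)
  p <- gbdtPredict(model, X)
  expect_equal(unname(p), plogis(c(-0.06, -0.06, 0.06, 0.06)))
})

test_that("training drives the loss down and separates separable toy data", {
  set.seed(11)
  X <- matrix(rnorm(200), 100, 2)
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] > 0)
  model <- gbdtFit(X, y, nTrees = 50L, learningRate = 0.3,
                   maxDepth = 2L, minLeaf = 1L)
  expect_true(all(diff(model@trainLoss) <= 1e-12))
  expect_equal(mean((gbdtPredict(model, X) > 0.5) == y), 1)

  # zero trees: the model predicts the class prior everywhere
  m0 <- gbdtFit(X, y, nTrees = 0L)
  expect_equal(unname(gbdtPredict(m0, X)), rep(mean(y), 100))
})

test_that("a depth-0 single tree equals prior plus one global Newton step", {
  set.seed(4)
  y <- rbinom(30, 1, 0.3)
  if (all(y == y[1])) y[1] <- 1 - y[1]
  X <- matrix(rnorm(60), 30, 2)
  model <- gbdtFit(X, y, nTrees = 1L, learningRate = 1, maxDepth = 0L)
  p0 <- mean(y)
  r <- y - p0
  step <- sum(r) / sum((y - r) * (1 - y + r))
  expect_equal(unname(gbdtPredict(model, X)),
               rep(plogis(log(p0 / (1 - p0)) + step), 30))
})

test_that("prediction equals an explicit tree-walk oracle and ignores sample order", {
  set.seed(21)
  X <- matrix(rnorm(300), 100, 3)
  colnames(X) <- c("a", "b", "c")
  y <- as.numeric(X[, 1] - X[, 3] + rnorm(100, 0, 0.3) > 0)
  model <- gbdtFit(X, y, nTrees = 15L, learningRate = 0.1)
  p <- gbdtPredict(model, X)
  expect_equal(unname(p), oracle_gbdt_predict(model, X), tolerance = 1e-12)

  # permutation invariance of the fit
  perm <- sample(100)
  m2 <- gbdtFit(X[perm, ], y[perm], nTrees = 15L, learningRate = 0.1)
  expect_equal(gbdtPredict(m2, X), p, tolerance = 1e-12)

  expect_error(gbdtPredict(model, X[, 1:2]), "match")
})

test_that("models survive a JSON round trip and reject foreign schemas", {
  set.seed(5)
  X <- matrix(rnorm(100), 50, 2)
  colnames(X) <- c("f1", "f2")
  y <- as.numeric(X[, 1] > 0)
  model <- gbdtFit(X, y, nTrees = 5L)
  path <- tempfile(fileext = ".json")
  writeGbdtModel(model, path)
  back <- readGbdtModel(path)
  expect_equal(gbdtPredict(back, X), gbdtPredict(model, X),
               tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other-1"), bad, auto_unbox = TRUE)
  expect_error(readGbdtModel(bad), "schema")
})

test_that("test AUC stays close to an established boosting reference", {
  skip_if_not_installed("xgboost")
  set.seed(31)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5)
  y <- as.numeric(X[, 1] + X[, 2]^2 - 1 + rnorm(n, 0, 0.5) > 0)
  tr <- 1:300; te <- 301:400
  model <- gbdtFit(X[tr, ], y[tr], nTrees = 80L, learningRate = 0.1,
                   maxDepth = 3L, minLeaf = 5L)
  p_ours <- gbdtPredict(model, X[te, ])
  dtrain <- xgboost::xgb.DMatrix(X[tr, ], label = y[tr])
  ref <- xgboost::xgb.train(params = list(eta = 0.1, max_depth = 3,
                                          objective = "binary:logistic",
                                          lambda = 0, min_child_weight = 1),
                            data = dtrain, nrounds = 80)
  p_ref <- predict(ref, xgboost::xgb.DMatrix(X[te, ]))
  auc_ours <- rocCurve(p_ours, y[te])@auc
  auc_ref <- rocCurve(p_ref, y[te])@auc
  expect_lt(abs(auc_ours - auc_ref), 0.05)
})
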