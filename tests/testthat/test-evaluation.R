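test_that("detection matching is greedy, one-to-one, and equals the oracle", {
  truth <- data.frame(image_id = c(1, 1, 2), row = c(50, 100, 60),
                      col = c(50, 100, 60))
  det <- data.frame(image_id = c(1, 1), row = c(50, 52), col = c(50, 51),
                    score = c(0.9, 0.8))
  out <- matchDetections(det, truth, 10)
  expect_true(out$tp[1])        # exact hit
  expect_false(out$tp[2])       # lesion already taken by higher score
  expect_equal(out$truth_id[1], 1L)

  # detections in the wrong image never match
  det2 <- data.frame(image_id = 2, row = 50, col = 50, score = 1)
  expect_false(matchDetections(det2, truth, 10)$tp)

  for (seed in 1:8) {
    set.seed(seed)
    truth <- data.frame(image_id = sample(1:3, 15, TRUE),
                        row = runif(15, 0, 200), col = runif(15, 0, 200))
    det <- data.frame(image_id = sample(1:3, 40, TRUE),
                      row = runif(40, 0, 200), col = runif(40, 0, 200),
                      score = runif(40))
    got <- matchDetections(det, truth, 30)
    expect_equal(got$tp, oracle_match(det, truth, 30))
  }
})

test_that("ROC curves behave at the extremes and match pair counting", {
  perfect <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(auc(perfect), 1)
  reversed <- rocCurve(c(0.2, 0.8), c(1, 0))
  expect_equal(auc(reversed), 0)
  expect_error(rocCurve(c(1, 2), c(1, 1)), "both classes")

  for (seed in 1:5) {
    set.seed(seed)
    scores <- round(runif(200), 2)   # rounding forces ties
    labels <- rbinom(200, 1, 0.4)
    r <- rocCurve(scores, labels)
    expect_equal(auc(r), oracle_auc(scores, labels), tolerance = 1e-12)
    # monotone from (0,0) to (1,1)
    expect_true(all(diff(r@fpr) >= 0) && all(diff(r@tpr) >= 0))
    expect_equal(c(r@fpr[1], r@tpr[1]), c(0, 0))
    expect_equal(c(max(r@fpr), max(r@tpr)), c(1, 1))
  }
})

test_that("the FROC of a hand-built two-image scenario equals its enumeration", {
  truth <- data.frame(image_id = c(1, 1, 2), row = c(50, 100, 60),
                      col = c(50, 100, 60))
  det <- data.frame(image_id = c(1, 1, 1, 2, 2),
                    row = c(50, 52, 100, 200, 61),
                    col = c(50, 51, 104, 200, 60),
                    score = c(0.9, 0.8, 0.7, 0.6, 0.5))
  froc <- frocCurve(det, truth, nImages = 2)
  # threshold sweep by hand: TP = (1,1,2,2,3), FP = (0,1,1,2,2)
  expect_equal(froc@sensitivity, c(0, 1, 1, 2, 2, 3) / 3)
  expect_equal(froc@fpi, c(0, 0, 1, 1, 2, 2) / 2)
  # step lookup at the seven reference FPIs
  expect_equal(unname(sensitivityAt(froc)),
               c(1 / 3, 1 / 3, 2 / 3, 1, 1, 1, 1))
  expect_equal(fscore(froc), (1 / 3 + 1 / 3 + 2 / 3 + 4) / 7)
  # partial-area arithmetic on the linear envelope (0,1/3)-(.5,2/3)-(1,1)
  seg1 <- (5 / 12 + 2 / 3) / 2 * 0.375
  seg2 <- (2 / 3 + 1) / 2 * 0.5
  expect_equal(froc@fauc, (seg1 + seg2 + 7) / (8 - 1 / 8))

  # degenerate sweeps
  allhit <- frocCurve(data.frame(image_id = c(1, 1, 2),
                                 row = truth$row, col = truth$col,
                                 score = c(0.9, 0.8, 0.7)),
                      truth, nImages = 2)
  expect_equal(unname(sensitivityAt(allhit)), rep(1, 7))
  expect_equal(fscore(allhit), 1)
  none <- frocCurve(det[0, ], truth, nImages = 2)
  expect_equal(unname(sensitivityAt(none)), rep(0, 7))
  expect_error(frocCurve(det, truth[0, ]), "lesions")
})

test_that("mean-sensitivity summaries reproduce published-row arithmetic", {
  row_a <- c(0.083, 0.104, 0.200, 0.257, 0.344, 0.394, 0.468)
  expect_equal(round(fscore(row_a), 3), 0.264)
  row_b <- c(0.335, 0.424, 0.496, 0.578, 0.634, 0.668, 0.696)
  expect_equal(round(fscore(row_b), 3), 0.547)
  expect_equal(fscore(rep(0.5, 7)), 0.5)
  expect_equal(fscore(c(rep(0, 6), 0.7)), 0.1)
  expect_error(fscore(1:3), "seven")
})

test_that("partial FROC area normalizes to [0,1] with closed-form checks", {
  flat1 <- new("FROCResult", fpi = c(0, 10), sensitivity = c(1, 1),
               thresholds = c(Inf, 0), sensAtFpi = rep(1, 7),
               fscore = 1, fauc = 0, nImages = 2L, nLesions = 3L)
  expect_equal(fauc(flat1), 1)
  expect_equal(fauc(flat1, "max_fpi"), (8 - 1 / 8) / 8)
  flat0 <- new("FROCResult", fpi = c(0, 10), sensitivity = c(0, 0),
               thresholds = c(Inf, 0), sensAtFpi = rep(0, 7),
               fscore = 0, fauc = 0, nImages = 2L, nLesions = 3L)
  expect_equal(fauc(flat0), 0)
  # piecewise-linear curve: area by explicit trapezoids
  pw <- new("FROCResult", fpi = c(0, 2, 8), sensitivity = c(0, 0.5, 0.8),
            thresholds = c(Inf, 1, 0), sensAtFpi = rep(0, 7),
            fscore = 0, fauc = 0, nImages = 1L, nLesions = 1L)
  y18 <- 0.125 / 2 * 0.5
  a1 <- (y18 + 0.5) / 2 * (2 - 0.125)
  a2 <- (0.5 + 0.8) / 2 * 6
  expect_equal(fauc(pw), (a1 + a2) / (8 - 1 / 8))
})

test_that("evaluation summaries serialize the expected fields", {
  truth <- data.frame(image_id = 1, row = 10, col = 10)
  det <- data.frame(image_id = 1, row = 10, col = 10, score = 0.9)
  froc <- frocCurve(det, truth, nImages = 1)
  roc <- rocCurve(c(0.9, 0.1), c(1, 0))
  s <- evaluationSummary(roc, froc)
  expect_equal(s$auc, 1)
  expect_equal(s$fscore, 1)
  expect_length(s$sensitivities, 7)
})
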