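# End-to-end orchestration: preprocess -> candidates -> features ->
# classify, plus labelling, training and cross-validation over image sets.

#' Preprocess one image and extract candidate features
#'
#' @param image row x col x 3 raw RGB array.
#' @param config pipeline configuration.
#' @return list with `pre` ([PreprocessedFundus-class]), `candidates`
#'   (data.frame), `features` (matrix, one row per candidate).
#' @export
processImage <- function(image, config = defaultConfig()) {
  pre <- preprocessFundus(image, config)
  det <- detectCandidates(pre, config)
  feats <- featureMatrix(greenChannel(pre), det$candidates, config)
  list(pre = pre, candidates = det$candidates, features = feats,
       mask = det$mask, vessels = det$vessels)
}

#' Label candidates against annotated lesion centers
#'
#' A candidate is positive if its centroid lies within `matchRadius` px of
#' an annotated lesion center (working frame); each lesion labels at most
#' one candidate (the nearest).
#'
#' @param candidates data.frame with `row`, `col`.
#' @param truth data.frame with `row`, `col` (working frame, 1-based).
#' @param matchRadius radius in px.
#' @return 0/1 vector, one entry per candidate.
#' @export
labelCandidates <- function(candidates, truth, matchRadius = 10) {
  labels <- numeric(nrow(candidates))
  if (!nrow(candidates) || !nrow(truth)) return(labels)
  taken <- logical(nrow(candidates))
  for (j in seq_len(nrow(truth))) {
    d2 <- (candidates$row - truth$row[j])^2 +
          (candidates$col - truth$col[j])^2
    d2[taken] <- Inf
    i <- which.min(d2)
    if (d2[i] <= matchRadius^2) {
      labels[i] <- 1
      taken[i] <- TRUE
    }
  }
  labels
}

# canonical feature subsets: salience + texture (30), descriptor block
# (10), and the combination (40)
.feature_subset <- function(features, set = c("cf", "tslt", "rgd")) {
  set <- match.arg(set)
  nm <- featureNames()
  cols <- switch(set, cf = nm, tslt = nm[1:30], rgd = nm[31:40])
  features[, cols, drop = FALSE]
}

#' Train the candidate classifier on an annotated image set
#'
#' Runs the candidate pipeline on every image, labels candidates against
#' the ground truth, pools them, and fits the boosted-tree classifier.
#'
#' @param images list of row x col x 3 arrays (or
#'   [SyntheticFundus-class] objects).
#' @param truth data.frame `image_id`, `row`, `col` (working frame,
#'   1-based), `image_id` indexing into `images`.
#' @param config pipeline configuration.
#' @param featureSet `"cf"` (all 40), `"tslt"` (salience + texture) or
#'   `"rgd"` (descriptor block only).
#' @return list with `model` ([GBDTModel-class]), pooled `features`,
#'   `labels`, and `perImage` (candidate tables).
#' @export
trainDetector <- function(images, truth, config = defaultConfig(),
                          featureSet = "cf") {
  proc <- lapply(images, function(im) {
    img <- if (is(im, "SyntheticFundus")) im@image else im
    processImage(img, config)
  })
  feats <- do.call(rbind, lapply(proc, `[[`, "features"))
  labels <- unlist(lapply(seq_along(proc), function(i) {
    labelCandidates(proc[[i]]$candidates,
                    truth[truth$image_id == i, , drop = FALSE],
                    config$match_radius)
  }))
  X <- .feature_subset(feats, featureSet)
  model <- gbdtFit(X, labels, config$n_trees, config$learning_rate,
                   config$max_depth, config$min_leaf)
  list(model = model, features = feats, labels = labels, perImage = proc)
}

#' Detect microaneurysms in one image
#'
#' @param image row x col x 3 raw RGB array.
#' @param model fitted [GBDTModel-class].
#' @param config pipeline configuration.
#' @param imageId value for the `image_id` column.
#' @return data.frame `image_id`, `row`, `col`, `area`, `score` (working
#'   frame, 1-based), one row per candidate.
#' @export
detectImage <- function(image, model, config = defaultConfig(),
                        imageId = 1L) {
  proc <- processImage(image, config)
  out <- data.frame(image_id = rep(imageId, nrow(proc$candidates)),
                    row = proc$candidates$row, col = proc$candidates$col,
                    area = proc$candidates$area,
                    score = numeric(nrow(proc$candidates)))
  if (nrow(out)) {
    fset <- if (length(model@featureNames) == 10L) "rgd"
            else if (length(model@featureNames) == 30L) "tslt" else "cf"
    out$score <- gbdtPredict(model, .feature_subset(proc$features, fset))
  }
  out
}

#' Cross-validated candidate classification on an image set
#'
#' Extracts candidates and features once, then performs k-fold
#' cross-validation by image: each fold's candidates are scored by a model
#' trained on the remaining folds. Pooled out-of-fold scores give the
#' candidate-level ROC and the lesion-level FROC.
#'
#' @param dataset list from [generateDataset()] (`images`, `truth`,
#'   `folds`).
#' @param config pipeline configuration.
#' @param featureSet `"cf"`, `"tslt"` or `"rgd"`.
#' @param processed optional precomputed list from [processImage()], one
#'   entry per image, to reuse across feature sets.
#' @return list with `roc` ([ROCResult-class]), `froc`
#'   ([FROCResult-class]), `scores`, `labels`, `detections`, `processed`.
#' @export
crossValidate <- function(dataset, config = defaultConfig(),
                          featureSet = "cf", processed = NULL) {
  images <- dataset$images
  folds <- dataset$folds
  if (is.null(processed))
    processed <- lapply(images, function(im) {
      img <- if (is(im, "SyntheticFundus")) im@image else im
      processImage(img, config)
    })
  labels <- lapply(seq_along(processed), function(i)
    labelCandidates(processed[[i]]$candidates,
                    dataset$truth[dataset$truth$image_id == i, ,
                                  drop = FALSE],
                    config$match_radius))
  scores <- vector("list", length(processed))
  for (k in sort(unique(folds))) {
    tr <- which(folds != k)
    te <- which(folds == k)
    Xtr <- do.call(rbind, lapply(tr, function(i) processed[[i]]$features))
    ytr <- unlist(labels[tr])
    model <- gbdtFit(.feature_subset(Xtr, featureSet), ytr, config$n_trees,
                     config$learning_rate, config$max_depth,
                     config$min_leaf)
    for (i in te) {
      f <- processed[[i]]$features
      scores[[i]] <- if (nrow(f))
        gbdtPredict(model, .feature_subset(f, featureSet)) else numeric(0)
    }
  }
  detections <- do.call(rbind, lapply(seq_along(processed), function(i) {
    cand <- processed[[i]]$candidates
    if (!nrow(cand)) return(NULL)
    data.frame(image_id = i, row = cand$row, col = cand$col,
               score = scores[[i]])
  }))
  allScores <- unlist(scores)
  allLabels <- unlist(labels)
  roc <- rocCurve(allScores, allLabels)
  froc <- frocCurve(detections, dataset$truth,
                    nImages = length(images), config = config)
  list(roc = roc, froc = froc, scores = allScores, labels = allLabels,
       detections = detections, processed = processed)
}
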