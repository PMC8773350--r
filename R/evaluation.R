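#' Match scored detections to annotated lesions
#'
#' Greedy one-to-one matching in descending score order: a detection is a
#' true positive if an unmatched annotated lesion center of the same image
#' lies within `matchRadius` px; every other detection is a false positive.
#' Each lesion is matched at most once.
#'
#' @param detections data.frame with columns `image_id`, `row`, `col`,
#'   `score`.
#' @param groundTruth data.frame with columns `image_id`, `row`, `col`.
#' @param matchRadius matching radius in working-frame px.
#' @return `detections` with added logical column `tp` and integer column
#'   `truth_id` (row index into `groundTruth`, NA for false positives).
#' @export
matchDetections <- function(detections, groundTruth, matchRadius = 10) {
  det <- detections
  det$tp <- logical(nrow(det))
  det$truth_id <- rep(NA_integer_, nrow(det))
  if (!nrow(det) || !nrow(groundTruth)) return(det)
  used <- logical(nrow(groundTruth))
  ord <- order(-det$score)
  for (i in ord) {
    cand <- which(!used & groundTruth$image_id == det$image_id[i])
    if (!length(cand)) next
    d2 <- (groundTruth$row[cand] - det$row[i])^2 +
          (groundTruth$col[cand] - det$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= matchRadius^2) {
      det$tp[i] <- TRUE
      det$truth_id[i] <- cand[j]
      used[cand[j]] <- TRUE
    }
  }
  det
}

#' Candidate-level ROC curve
#'
#' True- against false-positive rate over every score threshold, with the
#' area under the curve by the trapezoidal rule (which, over all thresholds,
#' equals the Mann-Whitney probability that a random positive outscores a
#' random negative, ties counting half).
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return a [ROCResult-class] object.
#' @export
rocCurve <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels disagree in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  tpr <- c(0, tp / P, 1)
  fpr <- c(0, fp / N, 1)
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCResult", fpr = fpr, tpr = tpr,
      thresholds = c(Inf, thr, -Inf), auc = a)
}

.REFERENCE_FPIS <- c(1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)

# Upper envelope of an FROC step curve: the best sensitivity achieved at
# each distinct FPI, nondecreasing in FPI.
.froc_envelope <- function(fpi, sens) {
  ux <- sort(unique(fpi))
  uy <- vapply(ux, function(x) max(sens[fpi <= x]), numeric(1))
  list(fpi = ux, sens = uy)
}

# Sensitivity at a target FPI: "step" takes the envelope value at the
# largest achieved FPI <= target (0 if none); "linear" interpolates
# between the bracketing operating points, clamping outside the curve.
.froc_at <- function(env, target, linear = FALSE) {
  if (linear) {
    if (target <= env$fpi[1]) return(env$sens[1])
    n <- length(env$fpi)
    if (target >= env$fpi[n]) return(env$sens[n])
    stats::approx(env$fpi, env$sens, xout = target)$y
  } else {
    ok <- which(env$fpi <= target)
    if (!length(ok)) 0 else env$sens[max(ok)]
  }
}

#' Lesion-level FROC curve
#'
#' Matches detections to lesions once (threshold-free, greedy by score via
#' [matchDetections()]), then sweeps the score threshold: at each threshold
#' sensitivity = TP / (total lesions) and FPI = FP / (number of images).
#' Sensitivities at the seven reference FPIs 1/8 ... 8 are read off the
#' curve by the `froc_interpolation` convention (`"step"`: the sensitivity
#' at the largest achieved FPI at or below the target, the conservative
#' choice; `"linear"`: linear interpolation between bracketing points) and
#' summarized by [fscore()] and [fauc()].
#'
#' @param detections data.frame (`image_id`, `row`, `col`, `score`), all
#'   images pooled.
#' @param groundTruth data.frame (`image_id`, `row`, `col`), one row per
#'   annotated lesion.
#' @param nImages number of evaluated images; defaults to the number of
#'   distinct `image_id`s in `groundTruth`.
#' @param config pipeline configuration (keys `match_radius`,
#'   `froc_interpolation`, `fauc_normalizer`).
#' @return a [FROCResult-class] object.
#' @export
frocCurve <- function(detections, groundTruth,
                      nImages = length(unique(groundTruth$image_id)),
                      config = defaultConfig()) {
  nLesions <- nrow(groundTruth)
  if (!nLesions) stop("ground truth contains no lesions", call. = FALSE)
  if (nImages < 1) stop("need at least one image", call. = FALSE)
  det <- matchDetections(detections, groundTruth, config$match_radius)
  if (nrow(det)) {
    thr <- sort(unique(det$score), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(det$tp & det$score >= t), numeric(1))
    fp <- vapply(thr, function(t) sum(!det$tp & det$score >= t), numeric(1))
  } else {
    thr <- numeric(0); tp <- numeric(0); fp <- numeric(0)
  }
  sens <- c(0, tp / nLesions)
  fpi <- c(0, fp / nImages)
  thresholds <- c(Inf, thr)
  env <- .froc_envelope(fpi, sens)
  linear <- identical(config$froc_interpolation, "linear")
  sensAt <- vapply(.REFERENCE_FPIS, function(target)
    .froc_at(env, target, linear = linear), numeric(1))
  names(sensAt) <- paste0("fpi_", c("1_8", "1_4", "1_2", "1", "2", "4", "8"))
  res <- new("FROCResult", fpi = fpi, sensitivity = sens,
             thresholds = thresholds, sensAtFpi = sensAt,
             fscore = mean(sensAt), fauc = 0,
             nImages = as.integer(nImages), nLesions = as.integer(nLesions))
  res@fauc <- fauc(res, normalizer = config$fauc_normalizer)
  res
}

#' Mean sensitivity at the reference FPIs
#'
#' The arithmetic mean of the sensitivities at FPI = 1/8, 1/4, 1/2, 1, 2,
#' 4 and 8 false positives per image.
#'
#' @param x a [FROCResult-class], or a numeric vector of seven
#'   sensitivities.
#' @return scalar score in \[0, 1\].
#' @examples
#' fscore(c(0.083, 0.104, 0.200, 0.257, 0.344, 0.394, 0.468))
#' @export
fscore <- function(x) {
  s <- if (is(x, "FROCResult")) x@sensAtFpi else x
  if (length(s) != 7L) stop("expected seven sensitivities", call. = FALSE)
  mean(s)
}

#' Normalized partial area under the FROC curve
#'
#' Trapezoidal area of sensitivity against FPI over \[1/8, 8\] (the curve
#' is step-continued to the evaluation bounds), normalized so a detector
#' with sensitivity 1 across the range scores 1. `normalizer = "range"`
#' (default) divides by 8 - 1/8; `"max_fpi"` divides by 8.
#'
#' @param froc a [FROCResult-class] object.
#' @param normalizer `"range"` or `"max_fpi"`.
#' @return scalar in \[0, 1\] (under `"range"`).
#' @export
fauc <- function(froc, normalizer = c("range", "max_fpi")) {
  normalizer <- match.arg(normalizer)
  lo <- 1 / 8; hi <- 8
  env <- .froc_envelope(froc@fpi, froc@sensitivity)
  at <- function(x) .froc_at(env, x, linear = TRUE)
  xs <- sort(unique(c(lo, hi, env$fpi[env$fpi > lo & env$fpi < hi])))
  ys <- vapply(xs, at, numeric(1))
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  area / if (normalizer == "range") hi - lo else hi
}

#' Summarize an evaluation into a plain list
#'
#' @param roc a [ROCResult-class] or NULL.
#' @param froc a [FROCResult-class] or NULL.
#' @return list with `auc`, `fscore`, `fauc` and the seven named
#'   sensitivities, ready for JSON export.
#' @export
evaluationSummary <- function(roc = NULL, froc = NULL) {
  out <- list()
  if (!is.null(roc)) out$auc <- roc@auc
  if (!is.null(froc)) {
    out$fscore <- froc@fscore
    out$fauc <- froc@fauc
    out$sensitivities <- as.list(froc@sensAtFpi)
  }
  out
}
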