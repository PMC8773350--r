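#' @import methods
NULL

#' Preprocessed fundus image
#'
#' Container for the output of [preprocessFundus()]: the resized,
#' contrast-enhanced, ROI-masked color raster together with its green
#' channel, the field-of-view (FOV) mask, and the resize factor needed to
#' map annotation coordinates between the original and working frames.
#'
#' Rasters are numeric matrices (or a row x col x 3 array for the color
#' image) indexed \[row, col\], intensities on the 0..255 scale and kept
#' real-valued internally; values are clipped and rounded to 8 bit only on
#' export.
#'
#' @slot ice row x col x 3 array, the enhanced, masked color image.
#' @slot green numeric matrix, the green channel of `ice`.
#' @slot roiMask binary matrix, 1 inside the (eroded) field of view.
#' @slot scale numeric, working width / original width.
#'
#' @seealso [preprocessFundus()], [greenChannel()], [roiMask()], [imageScale()]
#' @export
setClass("PreprocessedFundus",
  representation(ice = "array", green = "matrix", roiMask = "matrix",
                 scale = "numeric"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@ice)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "'ice' must be a row x col x 3 array")
    else {
      if (!identical(d[1:2], dim(object@green)))
        msg <- c(msg, "'green' dimensions must match 'ice'")
      if (!identical(d[1:2], dim(object@roiMask)))
        msg <- c(msg, "'roiMask' dimensions must match 'ice'")
    }
    if (length(object@scale) != 1L || object@scale <= 0)
      msg <- c(msg, "'scale' must be a positive scalar")
    if (!all(object@roiMask %in% c(0, 1)))
      msg <- c(msg, "'roiMask' must be binary")
    if (length(msg)) msg else TRUE
  })

#' Gradient-boosted decision-tree model
#'
#' Additive logistic model: an initial log-odds `f0` plus `nTrees`
#' regression trees whose leaf contributions are shrunk by `learningRate`.
#' Trees are stored as node tables (see [fitCart()]).
#'
#' @slot f0 numeric, initial log-odds (the logit of the training prevalence).
#' @slot trees list of regression trees, each a data.frame of nodes.
#' @slot learningRate numeric shrinkage applied to every leaf contribution.
#' @slot nTrees integer, number of boosting rounds.
#' @slot featureNames character, column names the model was trained on.
#' @slot trainLoss numeric, training log-loss after each round.
#'
#' @seealso [gbdtFit()], [gbdtPredict()]
#' @export
setClass("GBDTModel",
  representation(f0 = "numeric", trees = "list", learningRate = "numeric",
                 nTrees = "integer", featureNames = "character",
                 trainLoss = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@f0) != 1L || !is.finite(object@f0))
      msg <- c(msg, "'f0' must be a finite scalar")
    if (length(object@trees) != object@nTrees)
      msg <- c(msg, "'trees' length must equal 'nTrees'")
    if (object@learningRate <= 0)
      msg <- c(msg, "'learningRate' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Candidate-level ROC curve
#'
#' @slot fpr,tpr numeric vectors tracing the curve from (0, 0) to (1, 1).
#' @slot thresholds score thresholds, one per curve point.
#' @slot auc area under the curve by the trapezoidal rule.
#' @seealso [rocCurve()]
#' @export
setClass("ROCResult",
  representation(fpr = "numeric", tpr = "numeric", thresholds = "numeric",
                 auc = "numeric"))

#' Lesion-level FROC curve
#'
#' Sensitivity versus average false positives per image (FPI), with the two
#' summary indices: `fscore`, the mean sensitivity at the seven reference
#' FPI values 1/8, 1/4, 1/2, 1, 2, 4, 8; and `fauc`, the normalized partial
#' area under the curve between FPI 1/8 and 8.
#'
#' @slot fpi,sensitivity numeric vectors tracing the curve.
#' @slot thresholds score thresholds, one per point.
#' @slot sensAtFpi named numeric, sensitivity at the seven reference FPIs.
#' @slot fscore,fauc numeric summary indices.
#' @slot nImages,nLesions integer counts underlying the normalisations.
#' @seealso [frocCurve()], [fscore()], [fauc()]
#' @export
setClass("FROCResult",
  representation(fpi = "numeric", sensitivity = "numeric",
                 thresholds = "numeric", sensAtFpi = "numeric",
                 fscore = "numeric", fauc = "numeric",
                 nImages = "integer", nLesions = "integer"))

#' Synthetic fundus image with ground truth
#'
#' @slot image row x col x 3 array, 8-bit-scale RGB raster.
#' @slot maCenters data.frame with columns `row`, `col` (1-based, image frame).
#' @slot vesselPaths list of n x 2 matrices of vessel centerline points.
#' @slot spec the generator specification list used.
#' @seealso [generateFundus()]
#' @export
setClass("SyntheticFundus",
  representation(image = "array", maCenters = "data.frame",
                 vesselPaths = "list", spec = "list"))

setMethod("show", "PreprocessedFundus", function(object) {
  d <- dim(object@ice)
  cat("PreprocessedFundus:", d[1], "x", d[2], "px, scale",
      format(object@scale, digits = 4), "\n")
  cat("  FOV coverage:",
      format(100 * mean(object@roiMask), digits = 3), "% of frame\n")
})

setMethod("show", "GBDTModel", function(object) {
  cat("GBDTModel:", object@nTrees, "trees, learning rate",
      object@learningRate, ", f0 =", format(object@f0, digits = 4), "\n")
  if (length(object@trainLoss))
    cat("  final training log-loss:",
        format(utils::tail(object@trainLoss, 1), digits = 5), "\n")
})

setMethod("show", "ROCResult", function(object) {
  cat("ROCResult:", length(object@fpr), "points, AUC =",
      format(object@auc, digits = 4), "\n")
})

setMethod("show", "FROCResult", function(object) {
  cat("FROCResult:", object@nLesions, "lesions over", object@nImages,
      "images\n")
  cat("  Fscore =", format(object@fscore, digits = 3),
      " FAUC =", format(object@fauc, digits = 3), "\n")
})

setMethod("show", "SyntheticFundus", function(object) {
  d <- dim(object@image)
  cat("SyntheticFundus:", d[1], "x", d[2], "px,",
      nrow(object@maCenters), "MAs,", length(object@vesselPaths),
      "vessels\n")
})

#' Accessors for pipeline result objects
#'
#' @param object a [PreprocessedFundus-class], [ROCResult-class] or
#'   [FROCResult-class] object.
#' @return `greenChannel`: the green-channel matrix; `roiMask`: the binary
#'   FOV mask; `imageScale`: the resize factor; `enhancedImage`: the 3-channel
#'   array; `auc`: the ROC area; `sensitivityAt`: named sensitivities at the
#'   seven reference FPIs.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("greenChannel", function(object) standardGeneric("greenChannel"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("imageScale", function(object) standardGeneric("imageScale"))
#' @rdname accessors
#' @export
setGeneric("enhancedImage", function(object) standardGeneric("enhancedImage"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("sensitivityAt", function(object) standardGeneric("sensitivityAt"))

#' @rdname accessors
setMethod("greenChannel", "PreprocessedFundus", function(object) object@green)
#' @rdname accessors
setMethod("roiMask", "PreprocessedFundus", function(object) object@roiMask)
#' @rdname accessors
setMethod("imageScale", "PreprocessedFundus", function(object) object@scale)
#' @rdname accessors
setMethod("enhancedImage", "PreprocessedFundus", function(object) object@ice)
#' @rdname accessors
setMethod("auc", "ROCResult", function(object) object@auc)
#' @rdname accessors
setMethod("sensitivityAt", "FROCResult", function(object) object@sensAtFpi)

#' @rdname accessors
#' @export
setGeneric("maCenters", function(object) standardGeneric("maCenters"))
#' @rdname accessors
setMethod("maCenters", "SyntheticFundus", function(object) object@maCenters)
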