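#' Threshold the preprocessed green channel for dark structures
#'
#' Binary map of pixels strictly darker than `threshold` inside the FOV
#' mask. Used twice: with a higher threshold to capture connected vessel
#' trees, and with a lower threshold to capture putative microaneurysms
#' while admitting fewer spurious dark pixels.
#'
#' @param green green-channel matrix of a preprocessed image.
#' @param threshold gray threshold in \[0, 255\].
#' @param mask optional binary FOV matrix restricting the foreground; the
#'   black exterior of the field of view never becomes foreground.
#' @return binary matrix.
#' @export
thresholdLowGray <- function(green, threshold, mask = NULL) {
  .check_raster(green, "green")
  if (threshold < 0 || threshold > 255)
    stop("'threshold' must lie in [0, 255]", call. = FALSE)
  out <- (green < threshold) * 1
  if (!is.null(mask)) {
    .check_same_dim(green, mask, "green channel and mask")
    out <- out * (mask != 0)
  }
  out
}

#' Vessel mask by component-area filtering
#'
#' Retinal vessels form large connected domains in the high-threshold binary
#' image; this keeps only 8-connected components with area strictly greater
#' than `minArea` px, which is the vessel mask used for suppression.
#'
#' @param binaryHigh binary matrix from [thresholdLowGray()] at the higher
#'   threshold.
#' @param minArea strict area cutoff in px (components of exactly this area
#'   are removed).
#' @return binary matrix containing only the large components.
#' @export
vesselMask <- function(binaryHigh, minArea = 400L) {
  if (minArea < 0) stop("'minArea' must be >= 0", call. = FALSE)
  labels <- .label8(binaryHigh)
  n <- max(labels)
  if (n == 0L) return(labels * 0)
  areas <- tabulate(labels[labels > 0], n)
  keep <- which(areas > minArea)
  matrix(as.numeric(labels %in% keep), nrow(labels), ncol(labels))
}

#' Candidate mask: low-threshold foreground minus dilated vessels
#'
#' Removes the vessel mask, expanded with a k x k rectangular structuring
#' element so that vessel edges are eliminated too, from the low-threshold
#' binary image. What survives are small isolated dark regions - the
#' microaneurysm candidates.
#'
#' @param binaryLow binary matrix from the lower threshold.
#' @param vessels binary vessel matrix from [vesselMask()].
#' @param k side of the square dilation element (odd).
#' @return binary candidate matrix.
#' @export
candidateMask <- function(binaryLow, vessels, k = 5L) {
  .check_same_dim(binaryLow, vessels, "binary images")
  if (k < 1 || k %% 2 == 0) stop("'k' must be odd and >= 1", call. = FALSE)
  grown <- if (any(vessels != 0)) {
    brush <- matrix(1L, k, k)
    .from_ebi(EBImage::dilate(.as_ebi(vessels * 1), brush))
  } else vessels * 0
  (binaryLow != 0) * (grown == 0) * 1
}

#' Extract candidate regions from a binary mask
#'
#' Labels the candidate mask with 8-connectivity and reports every component
#' with area at least `minCandidateArea` px (the default 2 discards
#' single-pixel noise). Components are returned in deterministic row-major
#' order of their rounded centroids.
#'
#' @param mask binary candidate matrix.
#' @param minCandidateArea minimum component area kept, in px.
#' @return data.frame with columns `row`, `col` (1-based rounded centroid),
#'   `area`, `label`.
#' @export
extractCandidates <- function(mask, minCandidateArea = 2L) {
  labels <- .label8(mask)
  stats <- .component_stats(labels)
  stats <- stats[stats$area >= minCandidateArea, , drop = FALSE]
  rownames(stats) <- NULL
  stats[, c("row", "col", "area", "label")]
}

#' Extract a square window centered on a candidate
#'
#' Crops a `side` x `side` window around (`row`, `col`); windows overhanging
#' the image border are completed by symmetric reflection so near-border
#' candidates are never discarded.
#'
#' @param green raster matrix.
#' @param row,col 1-based center coordinates.
#' @param side odd window side in px.
#' @return `side` x `side` matrix.
#' @export
extractWindow <- function(green, row, col, side = 11L) {
  .check_raster(green, "green")
  if (side %% 2 == 0 || side < 1)
    stop("'side' must be odd and >= 1", call. = FALSE)
  if (row < 1 || row > nrow(green) || col < 1 || col > ncol(green))
    stop("window center outside the image", call. = FALSE)
  h <- (side - 1L) / 2L
  padded <- .reflect_pad(green, h)
  padded[row:(row + 2L * h), col:(col + 2L * h), drop = FALSE]
}

#' Candidate extraction stage
#'
#' Runs the full dual-threshold candidate extraction on a preprocessed
#' image: high-threshold vessel segmentation with area filtering, dilation
#' of the vessel mask, low-threshold segmentation, vessel subtraction, and
#' connected-component analysis.
#'
#' @param pre a [PreprocessedFundus-class] object.
#' @param config pipeline configuration; keys `high_threshold`,
#'   `low_threshold`, `vessel_min_area`, `vessel_dilation_size`,
#'   `min_candidate_area`.
#' @return list with `candidates` (data.frame as in [extractCandidates()]),
#'   `mask` (binary candidate matrix) and `vessels` (binary vessel matrix).
#' @export
detectCandidates <- function(pre, config = defaultConfig()) {
  stopifnot(is(pre, "PreprocessedFundus"))
  if (config$low_threshold > config$high_threshold)
    stop("'low_threshold' must not exceed 'high_threshold'", call. = FALSE)
  green <- greenChannel(pre)
  fov <- roiMask(pre)
  iht <- thresholdLowGray(green, config$high_threshold, fov)
  ilt <- thresholdLowGray(green, config$low_threshold, fov)
  ive <- vesselMask(iht, config$vessel_min_area)
  ibw <- candidateMask(ilt, ive, config$vessel_dilation_size)
  list(candidates = extractCandidates(ibw, config$min_candidate_area),
       mask = ibw, vessels = ive)
}
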