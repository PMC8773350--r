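#' Resize a fundus image to the working width
#'
#' Scales the raster so its width equals `referenceWidth` (default 1400 px),
#' preserving the aspect ratio; the height is rounded to the nearest pixel.
#' All later stages and all exported coordinates live in this working frame;
#' the returned `scale` maps original-frame annotation coordinates into it.
#'
#' @param image row x col x 3 numeric array (or a single-channel matrix) on
#'   the 0..255 scale.
#' @param referenceWidth target width in pixels.
#' @return list with `image` (resized raster, bilinear interpolation) and
#'   `scale` = referenceWidth / original width.
#' @examples
#' img <- array(128, c(60, 80, 3))
#' out <- resizeToReference(img, 40)
#' dim(out$image)  # 30 x 40 x 3
#' out$scale       # 0.5
#' @export
resizeToReference <- function(image, referenceWidth = 1400L) {
  if (referenceWidth < 1) stop("'referenceWidth' must be >= 1", call. = FALSE)
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1))
    stop("empty image", call. = FALSE)
  w0 <- d[2]
  scale <- referenceWidth / w0
  h <- max(1L, as.integer(round(d[1] * scale)))
  if (w0 == referenceWidth && h == d[1])
    return(list(image = image, scale = 1.0))
  resize1 <- function(m)
    .from_ebi(EBImage::resize(.as_ebi(m), w = referenceWidth, h = h))
  if (length(d) == 2L) {
    out <- resize1(image)
  } else {
    out <- array(0, c(h, referenceWidth, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- resize1(image[, , k])
  }
  list(image = out, scale = scale)
}

#' Enhancement parameters
#'
#' Parameters of the local contrast-normalisation transform applied to each
#' color channel: `alpha * I + tau * (Gaussian(sigma) * I) + gamma`, clipped
#' to \[0, 255\]. With the defaults `alpha = 4`, `tau = -4`, `gamma = 128`
#' any locally smooth region maps to 128, so uneven illumination and color
#' casts are removed while local contrast is amplified fourfold.
#'
#' @param alpha gain on the raw intensity.
#' @param tau gain on the Gaussian-blurred intensity (the local background).
#' @param gamma additive offset.
#' @param sigma Gaussian standard deviation in pixels; defaults to
#'   working width / 30.
#' @param referenceWidth used only to derive the default `sigma`.
#' @return list of validated parameters.
#' @export
enhancementParams <- function(alpha = 4, tau = -4, gamma = 128,
                              sigma = referenceWidth / 30,
                              referenceWidth = 1400L) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  list(alpha = alpha, tau = tau, gamma = gamma, sigma = sigma)
}

#' Contrast-enhance a fundus image
#'
#' Applies `alpha * I + tau * (Gaussian(sigma) * I) + gamma` per channel with
#' symmetric-reflection boundary handling for the convolution (the FOV rim,
#' where reflection is a poor model, is later erased by mask erosion). The
#' Gaussian kernel is truncated at 3 sigma. The result is clipped to
#' \[0, 255\] but kept real-valued.
#'
#' @param image raster array or matrix on the 0..255 scale.
#' @param params list from [enhancementParams()].
#' @return raster of the same shape.
#' @export
enhanceFundus <- function(image, params = enhancementParams()) {
  if (is.null(params$sigma) || params$sigma <= 0)
    stop("'sigma' must be positive", call. = FALSE)
  kernel <- .gaussian_kernel(params$sigma)
  enh1 <- function(m)
    .clip255(params$alpha * m + params$tau * .convolve_reflect(m, kernel) +
             params$gamma)
  d <- dim(image)
  if (length(d) == 2L) return(enh1(image))
  out <- image
  for (k in seq_len(d[3])) out[, , k] <- enh1(image[, , k])
  out
}

#' Segment the field-of-view mask
#'
#' Thresholds the red channel (brightest inside the FOV disc) of the resized
#' original image, keeps the largest 8-connected component and fills its
#' holes, yielding a binary region-of-interest mask that separates the
#' illuminated retina from the dark surround.
#'
#' @param image row x col x 3 array (raw intensities, 0..255) or a matrix,
#'   in which case that channel is thresholded directly.
#' @param fovThreshold intensity threshold.
#' @return binary matrix (1 inside the FOV).
#' @export
computeRoiMask <- function(image, fovThreshold = 20) {
  ch <- if (length(dim(image)) == 3L) image[, , 1] else image
  .check_raster(ch, "image")
  fg <- ch > fovThreshold
  if (!any(fg)) stop("empty ROI: no pixel above the FOV threshold",
                     call. = FALSE)
  labels <- .label8(fg)
  areas <- tabulate(labels[labels > 0], max(labels))
  biggest <- which.max(areas)
  mask <- (labels == biggest) * 1
  mask <- .from_ebi(EBImage::fillHull(.as_ebi(mask)))
  mask * 1
}

#' Mask an enhanced image with an eroded FOV
#'
#' Multiplies the enhanced raster by the FOV mask eroded with a disc
#' structuring element, zeroing the noisy rim that the enhancement produces
#' at the FOV boundary.
#'
#' @param enhanced raster array or matrix.
#' @param mask binary matrix.
#' @param discRadius erosion disc radius in px; 0 applies the mask as-is.
#' @param scale resize factor to record (see [PreprocessedFundus-class]).
#' @return a [PreprocessedFundus-class] object.
#' @export
applyMaskWithErosion <- function(enhanced, mask, discRadius = 8L,
                                 scale = 1.0) {
  d <- dim(enhanced)
  .check_same_dim(enhanced, mask, "enhanced image and mask")
  eroded <- if (discRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(discRadius) + 1L, "disc")
    .from_ebi(EBImage::erode(.as_ebi(mask * 1), brush))
  } else mask * 1
  if (length(d) == 2L) {
    ice <- array(0, c(d, 3))
    for (k in 1:3) ice[, , k] <- enhanced * eroded
  } else {
    ice <- enhanced
    for (k in seq_len(d[3])) ice[, , k] <- enhanced[, , k] * eroded
  }
  new("PreprocessedFundus", ice = ice, green = ice[, , 2],
      roiMask = eroded, scale = scale)
}

#' Preprocess a fundus image
#'
#' Full preprocessing chain: resize to the working width, contrast-enhance
#' each channel, segment the FOV on the resized original, and mask the
#' enhanced image with the eroded FOV. The returned object records the
#' resize factor so lesion annotations given in original coordinates can be
#' mapped into the working frame.
#'
#' @param image row x col x 3 array, raw RGB intensities on 0..255.
#' @param config pipeline configuration list; see [defaultConfig()]. Keys
#'   used: `reference_width`, `alpha`, `tau`, `gamma`, `sigma`,
#'   `fov_threshold`, `erosion_radius`.
#' @return a [PreprocessedFundus-class] object.
#' @examples
#' syn <- generateFundus(syntheticSpec(image_size = c(120, 120), n_mas = 3,
#'                                     seed = 1))
#' pre <- preprocessFundus(syn@image, defaultConfig(reference_width = 120))
#' pre
#' @export
preprocessFundus <- function(image, config = defaultConfig()) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || any(d[1:2] < 1))
    stop("'image' must be a non-empty row x col x 3 array", call. = FALSE)
  rs <- resizeToReference(image, config$reference_width)
  sigma <- if (!is.null(config$sigma)) config$sigma else
    config$reference_width / 30
  params <- enhancementParams(config$alpha, config$tau, config$gamma, sigma)
  enhanced <- enhanceFundus(rs$image, params)
  mask <- computeRoiMask(rs$image, config$fov_threshold)
  applyMaskWithErosion(enhanced, mask, config$erosion_radius, rs$scale)
}
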