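#' First-order salience features of a candidate patch
#'
#' Six statistics of the intensity histogram of an 11 x 11 patch centered
#' on the candidate: mean, standard deviation, normalized third central
#' moment, energy, entropy (bits) and contrast. Intensities are rounded to
#' the 256 integer gray levels for the histogram; the third moment is
#' divided by (L-1)^2 = 255^2 and the contrast is the smoothness statistic
#' R = 1 - 1 / (1 + sigma^2 / 255^2), both standard normalisations that keep
#' the features on comparable scales.
#'
#' @param patch numeric matrix on the 0..255 scale (any size; the pipeline
#'   uses 11 x 11).
#' @return named numeric of length 6:
#'   `mean`, `sd`, `third_moment`, `energy`, `entropy`, `contrast`.
#' @examples
#' salienceFeatures(matrix(100, 11, 11))  # degenerate: sd 0, energy 1
#' @export
salienceFeatures <- function(patch) {
  .check_raster(patch, "patch")
  v <- pmin(pmax(round(as.vector(patch)), 0), 255)
  p <- tabulate(v + 1L, 256L) / length(v)
  lev <- 0:255
  mu <- sum(lev * p)
  varp <- sum((lev - mu)^2 * p)
  mu3 <- sum((lev - mu)^3 * p) / 255^2
  energy <- sum(p^2)
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  contrast <- 1 - 1 / (1 + varp / 255^2)
  c(mean = mu, sd = sqrt(varp), third_moment = mu3, energy = energy,
    entropy = entropy, contrast = contrast)
}

# offsets at distance 1 as (drow, dcol); order fixed across the package
.glcm_offsets <- list(
  "0"   = c(0L, 1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Quantizes a patch uniformly to `levels` gray bins over \[0, 255\] and
#' counts co-occurring intensity pairs at distance 1 in one of the four
#' directions 0, 45, 90, 135 degrees. Pairs are counted in both directions
#' (symmetric GLCM) and the matrix is normalized to unit sum.
#'
#' @param patch numeric matrix on the 0..255 scale, side >= 2.
#' @param offset one of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param levels number of gray levels Ng (>= 2).
#' @return `levels` x `levels` matrix summing to 1.
#' @export
computeGlcm <- function(patch, offset = "0", levels = 8L) {
  .check_raster(patch, "patch")
  if (min(dim(patch)) < 2L) stop("patch side must be >= 2", call. = FALSE)
  if (levels < 2L) stop("'levels' must be >= 2", call. = FALSE)
  offset <- match.arg(as.character(offset), names(.glcm_offsets))
  d <- .glcm_offsets[[offset]]
  q <- matrix(pmin(floor(pmin(pmax(patch, 0), 255) / (256 / levels)),
                   levels - 1L), nrow(patch), ncol(patch))
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - d[1]):min(nr, nr - d[1])
  c1 <- max(1L, 1L - d[2]):min(nc, nc - d[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + d[1], c1 + d[2], drop = FALSE]
  tab <- table(factor(a, levels = 0:(levels - 1L)),
               factor(b, levels = 0:(levels - 1L)))
  counts <- matrix(as.numeric(tab), levels, levels)
  counts <- counts + t(counts)
  counts / sum(counts)
}

#' Haralick features of a normalized GLCM
#'
#' Six texture statistics of a symmetric, unit-sum co-occurrence matrix
#' p(i, j): correlation, inverse difference moment, difference variance
#' (the variance of the |i - j| distribution), entropy (natural log, with
#' 0 log 0 = 0), angular second moment, and contrast. A degenerate patch
#' with zero marginal variance reports correlation 0.
#'
#' @param glcm square nonnegative matrix summing to 1.
#' @return named numeric of length 6.
#' @export
haralickFeatures <- function(glcm) {
  ng <- nrow(glcm)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(glcm)
  mux <- sum(seq_len(ng) * px)
  muy <- mux  # symmetric GLCM: both marginals coincide
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  correlation <- if (sx == 0) 0 else
    (sum(i * j * glcm) - mux * muy) / (sx * sx)
  idm <- sum(glcm / (1 + (i - j)^2))
  k <- abs(i - j)
  pxy <- vapply(0:(ng - 1L), function(d) sum(glcm[k == d]), numeric(1))
  muk <- sum((0:(ng - 1L)) * pxy)
  diffvar <- sum(((0:(ng - 1L)) - muk)^2 * pxy)
  nz <- glcm[glcm > 0]
  entropy <- -sum(nz * log(nz))
  asm <- sum(glcm^2)
  contrast <- sum((i - j)^2 * glcm)
  c(correlation = correlation, idm = idm, diff_variance = diffvar,
    entropy = entropy, angular_moment = asm, contrast = contrast)
}

#' 24-dimensional texture block of a candidate patch
#'
#' [haralickFeatures()] of the patch GLCM at the four offsets, concatenated
#' in the fixed order 0, 45, 90, 135 degrees.
#'
#' @inheritParams computeGlcm
#' @return named numeric of length 24 (`<feature>_<offset>`).
#' @export
textureFeatures <- function(patch, levels = 8L) {
  out <- unlist(lapply(names(.glcm_offsets), function(o) {
    f <- haralickFeatures(computeGlcm(patch, o, levels))
    names(f) <- paste0(names(f), "_", o)
    f
  }))
  out
}
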