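# Internal raster helpers. Rasters are numeric matrices indexed [row, col]
# with intensities on the 0..255 scale (kept real-valued until export).
# EBImage stores images as [x = col, y = row], hence the transposes.

.as_ebi <- function(m) EBImage::Image(t(m))

.from_ebi <- function(img) t(EBImage::imageData(img))

#' @noRd
.check_raster <- function(m, name = "raster") {
  if (!is.matrix(m) || !is.numeric(m) || any(dim(m) < 1L))
    stop(sprintf("'%s' must be a non-empty numeric matrix", name), call. = FALSE)
  invisible(m)
}

.check_same_dim <- function(a, b, what = "rasters") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("%s must share dimensions (%s vs %s)", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  invisible(NULL)
}

# Symmetric (edge-including) reflection padding; pad must not exceed dim - 1.
.reflect_pad <- function(m, pad) {
  if (pad == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (pad > nr - 1L || pad > nc - 1L)
    stop("reflection pad exceeds raster size", call. = FALSE)
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1L))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1L))
  m[ri, ci, drop = FALSE]
}

# Isotropic Gaussian kernel truncated at `truncate` standard deviations,
# normalized to unit sum.
.gaussian_kernel <- function(sigma, truncate = 3) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Gaussian kernel of a fixed odd side (used by the ring gradient descriptor,
# where the kernel must match the central area exactly).
.gaussian_kernel_fixed <- function(side, sigma) {
  h <- (side - 1L) / 2L
  x <- (-h):h
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

# 2-D convolution with symmetric-reflection boundary handling, via EBImage's
# FFT filter on a padded copy (the circular wrap-around only touches the
# padding, which is cropped away).
.convolve_reflect <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  padded <- .reflect_pad(m, r)
  out <- .from_ebi(EBImage::filter2(.as_ebi(padded), t(kernel),
                                    boundary = "circular"))
  out[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; diagonal
# contacts between 4-components are merged with a union-find pass over the
# two diagonal shifts.
.label8 <- function(mask) {
  lab4 <- .from_ebi(EBImage::bwlabel(.as_ebi(mask != 0)))
  n <- max(lab4)
  if (n == 0L) return(lab4)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab4); nc <- ncol(lab4)
  # diagonal neighbour pairs: (r, c) with (r+1, c+1) and (r+1, c-1)
  a1 <- lab4[-nr, -nc]; b1 <- lab4[-1, -1]
  a2 <- lab4[-nr, -1];  b2 <- lab4[-1, -nc]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab4
  out[out > 0] <- relab[out[out > 0]]
  out
}

# Component areas and (row, col) centroids from a label matrix, ordered
# row-major by rounded centroid.
.component_stats <- function(labels) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(0), row = integer(0), col = integer(0),
                      area = integer(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab, n)
  crow <- as.integer(round(rowsum(rows, lab)[, 1] / area))
  ccol <- as.integer(round(rowsum(cols, lab)[, 1] / area))
  out <- data.frame(label = seq_len(n), row = crow, col = ccol, area = area)
  out[order(out$row, out$col), , drop = FALSE]
}

.clip255 <- function(m) pmin(pmax(m, 0), 255)
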