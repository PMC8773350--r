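# File-format glue: images move through EBImage (PNG/JPEG/TIFF), tables
# are plain CSV. Exported CSV coordinates are 0-based (row, col) in the
# resized working frame; R-side data.frames stay 1-based.

#' Read / write fundus images
#'
#' `readFundus` loads a PNG/JPEG/TIFF image as a row x col x 3 array on the
#' 0..255 scale (grayscale files are replicated across channels).
#' `writeFundus` clips, rounds to 8 bit and writes by file extension.
#'
#' @param path image file path.
#' @param image row x col x 3 array (or matrix) on the 0..255 scale.
#' @return `readFundus`: a row x col x 3 numeric array.
#' @export
readFundus <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  d <- dim(img)
  dat <- EBImage::imageData(img)
  if (length(d) == 2L) {
    m <- t(dat) * 255
    out <- array(0, c(dim(m), 3L))
    for (k in 1:3) out[, , k] <- m
  } else {
    nch <- min(d[3], 3L)
    out <- array(0, c(d[2], d[1], 3L))
    for (k in seq_len(nch)) out[, , k] <- t(dat[, , k]) * 255
    if (nch == 1L) for (k in 2:3) out[, , k] <- out[, , 1]
  }
  out
}

#' @rdname readFundus
#' @export
writeFundus <- function(image, path) {
  d <- dim(image)
  img8 <- round(.clip255(image)) / 255
  ebi <- if (length(d) == 2L) .as_ebi(img8) else {
    a <- array(0, c(d[2], d[1], d[3]))
    for (k in seq_len(d[3])) a[, , k] <- t(img8[, , k])
    EBImage::Image(a, colormode = "Color")
  }
  EBImage::writeImage(ebi, path)
  invisible(path)
}

#' Read / write detection and annotation tables
#'
#' Detections carry `image_id,row,col,score`, annotations `image_id,row,col`.
#' On disk the coordinates are 0-based in the working (resized) frame; in R
#' they are 1-based. `readAnnotations` can additionally rescale original-
#' frame annotations into the working frame with the `scale` factor stored
#' by [preprocessFundus()].
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @param scale factor applied to coordinates on load (default 1, i.e.
#'   the file is already in the working frame).
#' @return the read data.frame (1-based coordinates).
#' @name tables
NULL

#' @rdname tables
#' @export
writeDetections <- function(x, path) {
  out <- x
  out$row <- out$row - 1L
  out$col <- out$col - 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tables
#' @export
readDetections <- function(path) {
  x <- utils::read.csv(path)
  x$row <- x$row + 1L
  x$col <- x$col + 1L
  x
}

#' @rdname tables
#' @export
writeAnnotations <- function(x, path) {
  out <- x
  out$row <- out$row - 1L
  out$col <- out$col - 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tables
#' @export
readAnnotations <- function(path, scale = 1) {
  x <- utils::read.csv(path)
  x$row <- as.integer(round((x$row) * scale)) + 1L
  x$col <- as.integer(round((x$col) * scale)) + 1L
  x
}

#' Write a feature matrix as CSV
#'
#' @param features matrix from [featureMatrix()].
#' @param path CSV path.
#' @export
writeFeatures <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
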