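#' Names of the 40 candidate features, in canonical order
#'
#' Six first-order salience statistics, 24 co-occurrence texture features
#' (six Haralick statistics at offsets 0, 45, 90, 135 degrees), and the ten
#' ring gradient descriptors of [rgdParamGrid()]. The order is fixed and
#' shared by training and prediction.
#'
#' @return character vector of length 40.
#' @export
featureNames <- function() {
  grid <- rgdParamGrid()
  c(c("mean", "sd", "third_moment", "energy", "entropy", "contrast"),
    as.vector(outer(c("correlation", "idm", "diff_variance", "entropy",
                      "angular_moment", "contrast"),
                    names(.glcm_offsets),
                    paste, sep = "_")),
    paste0("rgd_b", grid$b, "_l", grid$l))
}

#' 40-dimensional feature vector of one candidate
#'
#' Salience and texture features are computed on the `patch_side` window
#' (default 11 x 11) and the ring descriptors on the `context_side` window
#' (default 23 x 23, wide enough for every parameter row), both extracted
#' from the preprocessed green channel with reflection at image borders.
#'
#' @param green preprocessed green-channel matrix.
#' @param row,col 1-based candidate center.
#' @param config pipeline configuration (keys `patch_side`, `context_side`,
#'   `glcm_levels`).
#' @return named numeric of length 40, ordered as [featureNames()].
#' @export
featureVector <- function(green, row, col, config = defaultConfig()) {
  patch <- extractWindow(green, row, col, config$patch_side)
  context <- extractWindow(green, row, col, config$context_side)
  out <- c(salienceFeatures(patch),
           textureFeatures(patch, config$glcm_levels),
           rgdVector(context))
  names(out) <- featureNames()
  out
}

#' Feature matrix for a set of candidates
#'
#' @param green preprocessed green-channel matrix.
#' @param candidates data.frame with columns `row`, `col` (from
#'   [extractCandidates()]).
#' @param config pipeline configuration.
#' @return numeric matrix, one row per candidate, 40 named columns.
#' @export
featureMatrix <- function(green, candidates, config = defaultConfig()) {
  out <- matrix(numeric(0), 0, 40L, dimnames = list(NULL, featureNames()))
  if (!nrow(candidates)) return(out)
  out <- t(vapply(seq_len(nrow(candidates)), function(i)
    featureVector(green, candidates$row[i], candidates$col[i], config),
    numeric(40L)))
  colnames(out) <- featureNames()
  out
}
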