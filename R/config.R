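#' Pipeline configuration
#'
#' Builds the full configuration list consumed by every pipeline stage.
#' All values have working defaults at the 1400-px reference width; pass
#' overrides as named arguments. Unknown keys are rejected.
#'
#' Keys (defaults in parentheses):
#' \describe{
#'   \item{reference_width (1400)}{working image width in px.}
#'   \item{alpha (4), tau (-4), gamma (128)}{enhancement coefficients.}
#'   \item{sigma (reference_width / 30)}{enhancement Gaussian SD in px.}
#'   \item{fov_threshold (20)}{red-channel threshold for the FOV mask.}
#'   \item{erosion_radius (8)}{disc radius eroding the FOV mask, px.}
#'   \item{high_threshold (110)}{vessel-capture gray threshold.}
#'   \item{low_threshold (95)}{candidate-capture gray threshold.}
#'   \item{vessel_min_area (400)}{strict area cutoff for vessel components.}
#'   \item{vessel_dilation_size (5)}{square dilation side for vessel margins.}
#'   \item{min_candidate_area (2)}{minimum surviving candidate area, px.}
#'   \item{glcm_levels (8)}{gray levels for co-occurrence matrices.}
#'   \item{patch_side (11)}{salience/texture patch side, px.}
#'   \item{context_side (23)}{ring-descriptor context window side, px.}
#'   \item{n_trees (80)}{boosting rounds.}
#'   \item{learning_rate (0.03)}{boosting shrinkage.}
#'   \item{max_depth (3)}{regression-tree depth limit.}
#'   \item{min_leaf (5)}{minimum samples per tree leaf.}
#'   \item{match_radius (10)}{lesion-matching radius in working-frame px.}
#'   \item{froc_interpolation ("step")}{"step" or "linear" sensitivity
#'     lookup at the reference FPIs.}
#'   \item{fauc_normalizer ("range")}{"range" divides the partial FROC area
#'     by 8 - 1/8 so a perfect detector scores 1; "max_fpi" divides by 8.}
#'   \item{seed (NULL)}{seed recorded for reproducibility.}
#' }
#'
#' @param ... named overrides of the keys above.
#' @return named list.
#' @examples
#' cfg <- defaultConfig(reference_width = 480, high_threshold = 112)
#' cfg$sigma  # 16: tracks the working width
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    reference_width = 1400L,
    alpha = 4, tau = -4, gamma = 128, sigma = NULL,
    fov_threshold = 20, erosion_radius = 8L,
    high_threshold = 110, low_threshold = 95,
    vessel_min_area = 400L, vessel_dilation_size = 5L,
    min_candidate_area = 2L,
    glcm_levels = 8L, patch_side = 11L, context_side = 23L,
    n_trees = 80L, learning_rate = 0.03, max_depth = 3L, min_leaf = 5L,
    match_radius = 10, froc_interpolation = "step",
    fauc_normalizer = "range",
    seed = NULL)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  if (is.null(cfg$sigma)) cfg$sigma <- cfg$reference_width / 30
  cfg
}

#' Read / write a pipeline configuration file
#'
#' Configurations round-trip losslessly through YAML; unknown keys in the
#' file are rejected with an error naming them.
#'
#' @param path file path.
#' @param config configuration list from [defaultConfig()].
#' @return `readPipelineConfig`: a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(defaultConfig, raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
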