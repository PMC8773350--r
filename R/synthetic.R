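# Seeded generator of fundus-like images with known ground truth: a bright
# field-of-view disc on black, a smooth illumination gradient, dark
# curvilinear vessels with Gaussian cross-profiles, small dark circular
# blobs (the microaneurysms) and additive Gaussian noise. Intensities are
# calibrated so that after contrast enhancement the retinal background sits
# at 128 and planted lesions fall below the low candidate threshold (95):
# the enhancement maps a local dip of depth d to roughly 128 - 4 d, so
# lesion depths of 25-60 give enhanced centers far below threshold while
# faint vessel stretches and noise produce the confusing dark fragments a
# classifier must reject.

#' Specification of a synthetic fundus image
#'
#' @param image_size c(rows, cols) in px.
#' @param fov_radius_frac FOV disc radius as a fraction of the smaller
#'   image dimension.
#' @param n_vessels number of vessels. Vessel lengths vary; short faint
#'   vessels deliberately escape the vessel-suppression stage and act as
#'   vessel-like negatives for the classifier.
#' @param vessel_width_px c(min, max) Gaussian cross-profile SD, px.
#' @param vessel_depth c(min, max) centerline intensity drop (raw scale).
#' @param n_mas number of microaneurysms.
#' @param ma_radius_px c(min, max) lesion radius in px (radius r gives a
#'   lesion roughly 2r + 1 px wide, i.e. 3-13 px over the default 1-6
#'   range, the width range the descriptor grid is sized for).
#' @param ma_depth c(min, max) central intensity drop (raw scale).
#' @param background_level mean retinal background intensity (green
#'   channel, raw scale).
#' @param illumination_gradient peak-to-center amplitude of the smooth
#'   illumination field.
#' @param noise_sd additive Gaussian noise SD (raw scale).
#' @param min_ma_vessel_distance_px minimum distance between a lesion
#'   center and any vessel centerline.
#' @param seed integer; the same spec and seed give bit-identical output.
#' @return validated spec list.
#' @export
syntheticSpec <- function(image_size = c(480L, 480L),
                          fov_radius_frac = 0.46,
                          n_vessels = 8L,
                          vessel_width_px = c(1.2, 2.5),
                          vessel_depth = c(12, 45),
                          n_mas = 10L,
                          ma_radius_px = c(1, 6),
                          ma_depth = c(25, 60),
                          background_level = 120,
                          illumination_gradient = 15,
                          noise_sd = 4,
                          min_ma_vessel_distance_px = 15,
                          seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               fov_radius_frac = fov_radius_frac,
               n_vessels = as.integer(n_vessels),
               vessel_width_px = vessel_width_px,
               vessel_depth = vessel_depth,
               n_mas = as.integer(n_mas),
               ma_radius_px = ma_radius_px,
               ma_depth = ma_depth,
               background_level = background_level,
               illumination_gradient = illumination_gradient,
               noise_sd = noise_sd,
               min_ma_vessel_distance_px = min_ma_vessel_distance_px,
               seed = as.integer(seed))
  if (any(spec$image_size < 32L))
    stop("image must be at least 32 x 32 px", call. = FALSE)
  if (spec$n_vessels < 0L || spec$n_mas < 0L)
    stop("counts must be nonnegative", call. = FALSE)
  if (any(spec$ma_depth <= 0) || any(spec$vessel_depth <= 0))
    stop("depths must be positive (structures are darker than background)",
         call. = FALSE)
  spec
}

# smooth random polyline across the FOV: random chord plus low-frequency
# sinusoidal wander, sampled at 1-px arc steps
.vessel_path <- function(nr, nc, ctr, radius, length_frac) {
  ang <- stats::runif(1, 0, 2 * pi)
  span <- radius * length_frac
  t0 <- stats::runif(1, -1 + length_frac / 2, 1 - length_frac / 2)
  mid <- ctr + (radius * t0) * c(sin(ang), cos(ang))
  dirv <- c(cos(ang), -sin(ang))
  normv <- c(sin(ang), cos(ang))
  npts <- max(8L, as.integer(2 * span))
  s <- seq(-span, span, length.out = npts)
  amp <- stats::runif(1, 0.02, 0.12) * span
  ph <- stats::runif(2, 0, 2 * pi)
  wig <- amp * sin(2 * pi * s / (2 * span) * stats::runif(1, 1, 3) + ph[1]) +
    0.4 * amp * sin(2 * pi * s / (2 * span) * stats::runif(1, 3, 6) + ph[2])
  cbind(mid[1] + s * dirv[1] + wig * normv[1],
        mid[2] + s * dirv[2] + wig * normv[2])
}

# accumulate a Gaussian-profile intensity drop along a path into `dip`
.draw_vessel <- function(dip, path, width, depth, depth_mod) {
  nr <- nrow(dip); nc <- ncol(dip)
  n <- nrow(path)
  arc <- seq(0, 1, length.out = n)
  d_along <- depth * (1 - depth_mod * (0.5 + 0.5 * sin(2 * pi * 2.3 * arc)))
  reach <- ceiling(3 * width)
  for (i in seq_len(n)) {
    r0 <- round(path[i, 1]); c0 <- round(path[i, 2])
    rlo <- max(1, r0 - reach); rhi <- min(nr, r0 + reach)
    clo <- max(1, c0 - reach); chi <- min(nc, c0 + reach)
    if (rhi < rlo || chi < clo) next
    rows <- rlo:rhi
    cols <- clo:chi
    d2 <- outer((rows - path[i, 1])^2, (cols - path[i, 2])^2, "+")
    contrib <- d_along[i] * exp(-d2 / (2 * width^2))
    dip[rows, cols] <- pmax(dip[rows, cols], contrib)
  }
  dip
}

#' Generate one synthetic fundus image with ground truth
#'
#' Deterministic in (spec, seed): the bright FOV disc, illumination field,
#' vessels, lesions and noise are drawn from the spec's own RNG stream.
#' Lesion centers are rejected-sampled to keep them inside the central FOV
#' and away from vessel centerlines and from each other; if no placement is
#' found the generation errors out.
#'
#' @param spec list from [syntheticSpec()].
#' @return a [SyntheticFundus-class] object; `maCenters` are 1-based
#'   (row, col) centers in the image frame.
#' @examples
#' syn <- generateFundus(syntheticSpec(image_size = c(160, 160), n_mas = 4,
#'                                     seed = 7))
#' syn
#' @export
generateFundus <- function(spec = syntheticSpec()) {
  set.seed(spec$seed)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  radius <- spec$fov_radius_frac * min(nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
  fov <- d2 <= radius^2

  # smooth illumination: tilted plane plus radial falloff
  tilt <- stats::runif(2, -1, 1)
  illum <- spec$illumination_gradient *
    (tilt[1] * (rr - ctr[1]) / nr + tilt[2] * (cc - ctr[2]) / nc -
       0.5 * d2 / radius^2)
  green <- spec$background_level + illum

  # vessels: mix of long main vessels and shorter faint segments
  dip <- matrix(0, nr, nc)
  paths <- list()
  if (spec$n_vessels > 0L) {
    for (v in seq_len(spec$n_vessels)) {
      long <- v <= ceiling(spec$n_vessels / 2)
      length_frac <- if (long) stats::runif(1, 1.2, 1.8)
                     else stats::runif(1, 0.08, 0.3)
      width <- stats::runif(1, spec$vessel_width_px[1],
                            spec$vessel_width_px[2])
      depth <- if (long)
        stats::runif(1, mean(spec$vessel_depth), spec$vessel_depth[2])
      else stats::runif(1, spec$vessel_depth[1], mean(spec$vessel_depth))
      path <- .vessel_path(nr, nc, ctr, radius, length_frac)
      dip <- .draw_vessel(dip, path, width, depth,
                          depth_mod = stats::runif(1, 0, 0.35))
      paths[[v]] <- path
    }
  }
  green <- green - dip

  # microaneurysms: circular Gaussian dips, kept clear of vessels, the FOV
  # rim, and one another
  centers <- matrix(numeric(0), 0, 2)
  if (spec$n_mas > 0L) {
    allpts <- if (length(paths)) do.call(rbind, paths) else
      matrix(numeric(0), 0, 2)
    maxTry <- 200L * spec$n_mas
    tries <- 0L
    while (nrow(centers) < spec$n_mas) {
      tries <- tries + 1L
      if (tries > maxTry)
        stop("could not place all microaneurysms; relax the spec",
             call. = FALSE)
      u <- stats::runif(2)
      r <- radius * 0.8 * sqrt(u[1])
      a <- 2 * pi * u[2]
      pt <- c(ctr[1] + r * sin(a), ctr[2] + r * cos(a))
      if (nrow(allpts) &&
          min((allpts[, 1] - pt[1])^2 + (allpts[, 2] - pt[2])^2) <
            spec$min_ma_vessel_distance_px^2) next
      if (nrow(centers) &&
          min((centers[, 1] - pt[1])^2 + (centers[, 2] - pt[2])^2) <
            (2 * 13)^2) next
      pt <- round(pt)
      centers <- rbind(centers, pt)
      mr <- stats::runif(1, spec$ma_radius_px[1], spec$ma_radius_px[2])
      md <- stats::runif(1, spec$ma_depth[1], spec$ma_depth[2])
      sig <- (mr + 0.5) / 1.6
      reach <- ceiling(4 * sig)
      rows <- max(1, pt[1] - reach):min(nr, pt[1] + reach)
      cols <- max(1, pt[2] - reach):min(nc, pt[2] + reach)
      dd2 <- outer((rows - pt[1])^2, (cols - pt[2])^2, "+")
      green[rows, cols] <- green[rows, cols] - md * exp(-dd2 / (2 * sig^2))
    }
  }

  if (spec$noise_sd > 0)
    green <- green + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)

  green[!fov] <- 0
  green <- .clip255(green)
  red <- .clip255(green * 1.35 + 45)
  blue <- .clip255(green * 0.4)
  red[!fov] <- 0; blue[!fov] <- 0
  img <- array(0, c(nr, nc, 3))
  img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue

  new("SyntheticFundus", image = img,
      maCenters = if (nrow(centers))
        data.frame(row = as.integer(centers[, 1]),
                   col = as.integer(centers[, 2]))
      else data.frame(row = integer(0), col = integer(0)),
      vesselPaths = paths, spec = spec)
}

#' Generate isolated 23 x 23 patch fixtures
#'
#' Small context windows of the three archetypes the ring descriptor must
#' separate: `"ma"` - a dark Gaussian blob at the center on a clean
#' background; `"vessel"` - a dark line through the center at a random
#' angle, extending through the surrounding annulus; `"background"` -
#' noise only. Intensities are on the enhanced scale (background near 128).
#'
#' @param kind `"ma"`, `"vessel"` or `"background"`.
#' @param n number of fixtures.
#' @param seed RNG seed.
#' @param side window side (odd, default 23).
#' @param depth c(min, max) intensity drop of the structure (enhanced
#'   scale).
#' @param noise_sd additive noise SD.
#' @return list of `side` x `side` matrices.
#' @export
generatePatchFixtures <- function(kind = c("ma", "vessel", "background"),
                                  n = 1L, seed = 1L, side = 23L,
                                  depth = c(40, 90), noise_sd = 2) {
  kind <- match.arg(kind)
  set.seed(seed)
  h <- (side - 1) / 2
  rr <- matrix(seq_len(side), side, side)
  cc <- t(rr)
  lapply(seq_len(n), function(i) {
    m <- matrix(128, side, side)
    d <- stats::runif(1, depth[1], depth[2])
    if (kind == "ma") {
      sig <- stats::runif(1, 1.0, 2.5)
      d2 <- (rr - h - 1)^2 + (cc - h - 1)^2
      m <- m - d * exp(-d2 / (2 * sig^2))
    } else if (kind == "vessel") {
      ang <- stats::runif(1, 0, pi)
      w <- stats::runif(1, 1.0, 2.0)
      dist <- abs((rr - h - 1) * cos(ang) - (cc - h - 1) * sin(ang))
      m <- m - d * exp(-dist^2 / (2 * w^2))
    }
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(side^2, 0, noise_sd), side, side)
    .clip255(m)
  })
}

#' Generate a reproducible multi-image dataset with folds
#'
#' Draws `nImages` synthetic fundus images from a spec template (per-image
#' seeds derived deterministically from `seed`) and assigns a round-robin
#' fold label for cross-validation.
#'
#' @param nImages number of images (>= number of folds).
#' @param spec template from [syntheticSpec()]; its `seed` is overridden
#'   per image.
#' @param seed master seed.
#' @param nFolds cross-validation folds (default 5).
#' @return list with `images` (list of [SyntheticFundus-class]), `truth`
#'   (data.frame `image_id`, `row`, `col` pooled over images) and `folds`
#'   (integer vector, one entry per image).
#' @export
generateDataset <- function(nImages, spec = syntheticSpec(), seed = 1L,
                            nFolds = 5L) {
  if (nImages < nFolds)
    stop("need at least as many images as folds", call. = FALSE)
  seeds <- seed * 1000L + seq_len(nImages)
  images <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- as.integer(s %% .Machine$integer.max)
    generateFundus(sp)
  })
  truth <- do.call(rbind, lapply(seq_len(nImages), function(i) {
    m <- images[[i]]@maCenters
    if (!nrow(m)) return(NULL)
    data.frame(image_id = i, row = m$row, col = m$col)
  }))
  if (is.null(truth))
    truth <- data.frame(image_id = integer(0), row = integer(0),
                        col = integer(0))
  folds <- rep(seq_len(nFolds), length.out = nImages)
  list(images = images, truth = truth, folds = folds)
}
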