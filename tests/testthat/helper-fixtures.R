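# Shared fixtures, generated in code. Working scale for synthetic tests is
# a 480-px frame; the config mirrors the 1400-px defaults with the
# resolution-dependent knobs scaled accordingly.

test_config <- function(...) {
  defaultConfig(reference_width = 480L, erosion_radius = 3L, ...)
}

# synthetic disc image: constant intensity inside a centered FOV disc
disc_image <- function(n = 120L, value = 100, radius = 0.45 * n) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  inside <- (rr - (n + 1) / 2)^2 + (cc - (n + 1) / 2)^2 <= radius^2
  ch <- matrix(0, n, n)
  ch[inside] <- value
  img <- array(0, c(n, n, 3))
  for (k in 1:3) img[, , k] <- ch
  list(image = img, inside = inside)
}

random_patch <- function(n = 11L, seed = 1L) {
  set.seed(seed)
  matrix(runif(n * n, 0, 255), n, n)
}

# one processed synthetic dataset shared across expensive tests
.cache <- new.env(parent = emptyenv())

cached_benchmark <- function() {
  if (is.null(.cache$bench)) {
    cfg <- test_config()
    ds <- generateDataset(40L, syntheticSpec(), seed = 42L)
    cv_cf <- crossValidate(ds, cfg, "cf")
    cv_tslt <- crossValidate(ds, cfg, "tslt", processed = cv_cf$processed)
    .cache$bench <- list(cfg = cfg, ds = ds, cf = cv_cf, tslt = cv_tslt)
  }
  .cache$bench
}
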