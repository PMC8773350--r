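test_that("low-gray thresholding is strict and honors the FOV mask", {
  g <- matrix(128, 20, 20)
  expect_true(all(thresholdLowGray(g, 110) == 0))
  g[5, 7] <- 50
  out <- thresholdLowGray(g, 110)
  expect_equal(which(out == 1), (7 - 1) * 20 + 5)
  # gradient ramp: exactly the values below the threshold
  ramp <- matrix(rep(0:255, length.out = 256), 16, 16)
  expect_equal(sum(thresholdLowGray(ramp, 100)), sum(ramp < 100))
  # FOV restriction: dark exterior never becomes foreground
  mask <- matrix(0, 20, 20); mask[5:15, 5:15] <- 1
  dark <- matrix(0, 20, 20)
  expect_equal(sum(thresholdLowGray(dark, 110, mask)), 11 * 11)
  expect_error(thresholdLowGray(g, 300), "threshold")
})

test_that("vessel mask keeps only components strictly larger than the cutoff", {
  m <- matrix(0, 60, 60)
  m[2:26, 2:21] <- 1            # area 500
  out <- vesselMask(m, 400)
  expect_equal(sum(out), 500)

  m2 <- matrix(0, 60, 60)
  m2[2:21, 2:21] <- 1           # area 400: boundary case, removed
  expect_equal(sum(vesselMask(m2, 400)), 0)

  # random blobs against the flood-fill + area-filter oracle
  for (seed in 1:5) {
    set.seed(seed)
    m3 <- matrix(rbinom(40 * 40, 1, 0.35), 40, 40)
    got <- vesselMask(m3, 10)
    lab <- oracle_label8(m3)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas > 10)
    expect_equal(got, matrix(as.numeric(lab %in% keep), 40, 40))
  }
})

test_that("candidate mask removes everything within the dilated vessels", {
  ilt <- matrix(0, 40, 40)
  ilt[10:11, 10:11] <- 1        # isolated blob, far from vessels
  ilt[20:21, 30:31] <- 1        # blob touching the vessel
  vessels <- matrix(0, 40, 40)
  vessels[15:25, 28] <- 1
  out <- candidateMask(ilt, vessels, 5L)
  expect_equal(sum(out[10:11, 10:11]), 4)   # survives
  expect_equal(sum(out[20:21, 30]), 0)      # within dilation reach: removed
  expect_equal(sum(out[20:21, 31]), 2)      # beyond the 2 px margin: kept

  # random masks against a max-filter dilation + logical-and oracle
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rbinom(900, 1, 0.2), 30, 30)
    v <- matrix(rbinom(900, 1, 0.05), 30, 30)
    expect_equal(candidateMask(a, v, 5L),
                 a * (1 - oracle_dilate(v, 5)))
  }
  expect_error(candidateMask(ilt, vessels[1:20, ], 5L), "dimension")
  expect_error(candidateMask(ilt, vessels, 4L), "odd")
})

test_that("candidate extraction filters tiny areas and reports centroids", {
  m <- matrix(0, 30, 30)
  m[2, 2] <- 1                      # area 1 -> dropped
  m[5, 28] <- 1                     # area 1 -> dropped
  m[10:12, 10:12] <- 1              # area 9
  m[20, 5:11] <- 1                  # area 7
  m[25, 25] <- 1; m[26, 26] <- 1    # area 2 (diagonal, 8-connected)
  out <- extractCandidates(m, 2L)
  expect_equal(nrow(out), 3)
  expect_true(all(out$area >= 2))
  sq <- out[out$area == 9, ]
  expect_equal(c(sq$row, sq$col), c(11, 11))
  ln <- out[out$area == 7, ]
  expect_equal(c(ln$row, ln$col), c(20, 8))
  # deterministic row-major ordering
  expect_equal(out$row, sort(out$row))
  expect_equal(nrow(extractCandidates(matrix(0, 5, 5))), 0)
})

test_that("window extraction crops interior and reflects at borders", {
  g <- matrix(seq_len(400), 20, 20)
  w <- extractWindow(g, 10, 10, 11)
  expect_equal(w, g[5:15, 5:15])
  wb <- extractWindow(g, 2, 2, 11)
  expect_identical(dim(wb), c(11L, 11L))
  # reflection: the window's far corner mirrors interior values
  expect_equal(wb[6, 6], g[2, 2])     # center preserved
  expect_equal(wb[1, 1], g[4, 4])     # mirrored interior value
  wc <- extractWindow(matrix(9, 15, 15), 8, 8, 11)
  expect_true(all(wc == 9))
  expect_error(extractWindow(g, 0, 5, 11), "center")
  expect_error(extractWindow(g, 5, 5, 10), "odd")
})

test_that("lowering the low threshold only adds candidate pixels; raising the area cutoff only removes vessels", {
  set.seed(7)
  g <- matrix(runif(60 * 60, 60, 160), 60, 60)
  m1 <- thresholdLowGray(g, 95)
  m2 <- thresholdLowGray(g, 90)
  expect_true(all(m2 <= m1))
  binary <- matrix(rbinom(60 * 60, 1, 0.4), 60, 60)
  v1 <- vesselMask(binary, 20)
  v2 <- vesselMask(binary, 60)
  expect_true(all(v2 <= v1))
})

test_that("candidates never overlap the dilated vessel mask and counts match the oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    ilt <- matrix(rbinom(2500, 1, 0.1), 50, 50)
    ive <- matrix(0, 50, 50)
    ive[sample(2500, 40)] <- 1
    ibw <- candidateMask(ilt, ive, 5L)
    dil <- oracle_dilate(ive, 5)
    cand <- extractCandidates(ibw, 2L)
    # nothing in the candidate mask may touch the dilated vessels
    expect_equal(sum(ibw * dil), 0)
    # candidate count equals oracle component count minus small components
    lab <- oracle_label8(ibw)
    areas <- tabulate(lab[lab > 0])
    expect_equal(nrow(cand), sum(areas >= 2))
  }
})
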