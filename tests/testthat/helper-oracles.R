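# Independent brute-force oracles. Each recomputes a quantity by the most
# direct method available (dense loops, explicit enumeration, closed
# forms), sharing no code with the implementation it checks.

# dense spatial convolution with symmetric-reflection boundary
oracle_convolve <- function(m, kernel) {
  r <- (nrow(kernel) - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {
    # symmetric (edge-including) reflection of an out-of-range index
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- reflect(i + di, nr)
      jj <- reflect(j + dj, nc)
      acc <- acc + m[ii, jj] * kernel[di + r + 1, dj + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

# flood-fill connected-component labelling (8-connectivity)
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] != 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] != 0 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# max-filter dilation with a k x k rectangle
oracle_dilate <- function(mask, k) {
  h <- (k - 1) / 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- max(1, i - h):min(nr, i + h)
    cs <- max(1, j - h):min(nc, j + h)
    out[i, j] <- max(mask[rs, cs])
  }
  out
}

# GLCM by explicit pair enumeration (symmetric, normalized)
oracle_glcm <- function(patch, drow, dcol, levels) {
  q <- pmin(floor(pmin(pmax(patch, 0), 255) / (256 / levels)), levels - 1)
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + drow; jj <- j + dcol
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
      a <- q[i, j] + 1; b <- q[ii, jj] + 1
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# the six co-occurrence statistics by direct summation
oracle_haralick <- function(p) {
  ng <- nrow(p)
  corr_num <- 0; idm <- 0; ent <- 0; asm <- 0; contr <- 0
  px <- rowSums(p)
  mux <- sum((1:ng) * px)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px))
  pxy <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    corr_num <- corr_num + i * j * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
    asm <- asm + p[i, j]^2
    contr <- contr + (i - j)^2 * p[i, j]
    k <- abs(i - j)
    pxy[k + 1] <- pxy[k + 1] + p[i, j]
  }
  muk <- sum((0:(ng - 1)) * pxy)
  dv <- sum(((0:(ng - 1)) - muk)^2 * pxy)
  corr <- if (sx == 0) 0 else (corr_num - mux * mux) / (sx * sx)
  c(correlation = corr, idm = idm, diff_variance = dv, entropy = ent,
    angular_moment = asm, contrast = contr)
}

# ring gradient descriptor by naive enumeration of every box on the ring
oracle_rgd <- function(context, b, l, sigma) {
  n <- nrow(context)
  ctr <- (n + 1) / 2
  h <- (l - 1) / 2
  lo <- -(h + b); hi <- h + 1
  starts <- rbind(
    cbind(lo, lo:h), cbind(lo:h, hi),
    cbind(hi, hi:(lo + 1)), cbind(hi:(lo + 1), lo))
  means <- apply(starts, 1, function(s) {
    rows <- (ctr + s[1]):(ctr + s[1] + b - 1)
    cols <- (ctr + s[2]):(ctr + s[2] + b - 1)
    mean(context[rows, cols])
  })
  xs <- (-h):h
  g <- outer(exp(-xs^2 / (2 * sigma^2)), exp(-xs^2 / (2 * sigma^2)))
  g <- g / sum(g)
  center <- context[(ctr - h):(ctr + h), (ctr - h):(ctr + h)]
  min(means) - sum(center * g)
}

# histogram-based first-order statistics, independent arithmetic
oracle_salience <- function(patch) {
  v <- pmin(pmax(round(as.vector(patch)), 0), 255)
  n <- length(v)
  counts <- table(factor(v, levels = 0:255))
  p <- as.numeric(counts) / n
  m <- sum((0:255) * p)
  va <- sum(((0:255) - m)^2 * p)
  c(mean = m, sd = sqrt(va),
    third_moment = sum(((0:255) - m)^3 * p) / 255^2,
    energy = sum(p^2),
    entropy = -sum(ifelse(p > 0, p * log2(p), 0)),
    contrast = 1 - 1 / (1 + va / 255^2))
}

# Mann-Whitney AUC by pair counting (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# walk a flat node table explicitly for one sample
oracle_tree_walk <- function(tree, x) {
  id <- 1
  while (tree$feature[id] > 0) {
    id <- if (x[tree$feature[id]] <= tree$threshold[id])
      tree$left[id] else tree$right[id]
  }
  tree$value[id]
}

oracle_gbdt_predict <- function(model, X) {
  sapply(seq_len(nrow(X)), function(i) {
    f <- model@f0
    for (tree in model@trees)
      f <- f + model@learningRate * oracle_tree_walk(tree, X[i, ])
    1 / (1 + exp(-f))
  })
}

# greedy score-ordered matching, re-derived independently
oracle_match <- function(det, truth, radius) {
  used <- rep(FALSE, nrow(truth))
  tp <- rep(FALSE, nrow(det))
  for (i in order(det$score, decreasing = TRUE)) {
    best <- NA; bestd <- Inf
    for (j in seq_len(nrow(truth))) {
      if (used[j] || truth$image_id[j] != det$image_id[i]) next
      d <- sqrt((truth$row[j] - det$row[i])^2 +
                (truth$col[j] - det$col[i])^2)
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (!is.na(best) && bestd <= radius) {
      tp[i] <- TRUE
      used[best] <- TRUE
    }
  }
  tp
}
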