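# Independent brute-force oracles. Each is a literal transcription of the
# defining formula or an exhaustive enumeration, deliberately written
# with plain loops and no code shared with the package internals.

# scalar re-derivation of CT windowing
oracle_normalize <- function(px, slope, intercept, wc, ww) {
  out <- matrix(0, nrow(px), ncol(px))
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      hu <- px[i, j] * slope + intercept
      v <- (hu - (wc - ww / 2)) / ww
      v <- min(max(v, 0), 1)
      out[i, j] <- floor(v * 255 + 0.5)
    }
  }
  out
}

# even-odd point-in-polygon, one pixel at a time
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# exhaustive search over all (row, col, side) triples
oracle_inscribed_square <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  best <- c(NA, NA, 0)
  for (side in seq_len(min(nr, nc))) {
    for (r in seq_len(nr - side + 1)) {
      for (c in seq_len(nc - side + 1)) {
        if (all(mask[r:(r + side - 1), c:(c + side - 1)]))
          if (side > best[3]) best <- c(r, c, side)
      }
    }
  }
  best
}

# per-pixel disc morphology
oracle_dilate <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di^2 + dj^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc && mask[ii, jj])
        out[i, j] <- TRUE
    }
  }
  out
}

oracle_erode <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di^2 + dj^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      on <- ii >= 1 && jj >= 1 && ii <= nr && jj <= nc && mask[ii, jj]
      if (!on) out[i, j] <- FALSE
    }
  }
  out
}

# brute-force co-occurrence pair counting
oracle_glcm <- function(q, angle, distance, levels = 16) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      ii <- i + off[1]; jj <- j + off[2]
      if (ii >= 1 && jj >= 1 && ii <= nrow(q) && jj <= ncol(q)) {
        a <- q[i, j] + 1; b <- q[ii, jj] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P / sum(P)
}

# literal Haralick transcription with explicit double loops
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  l2 <- function(p) if (p > 0) log2(p) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  vx <- 0
  for (i in 1:ng) vx <- vx + (i - mux)^2 * px[i]
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  contrast <- 0; dissim <- 0; homog <- 0; homogn <- 0; energy <- 0
  entropy <- 0; maxp <- 0; shade <- 0; prom <- 0; varh <- 0; cor <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    homog <- homog + p / (1 + (i - j)^2)
    homogn <- homogn + p / (1 + (i - j)^2 / ng^2)
    energy <- energy + p^2
    entropy <- entropy - p * l2(p)
    maxp <- max(maxp, p)
    shade <- shade + (i + j - mux - muy)^3 * p
    prom <- prom + (i + j - mux - muy)^4 * p
    varh <- varh + (i - mux)^2 * p
    cor <- cor + i * j * p
  }
  cor <- if (vx > 1e-12) (cor - mux * muy) / vx else 1
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) { sa <- sa + k * psum[k]; se <- se - psum[k] * l2(psum[k]) }
  sv <- 0
  for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  mud <- 0
  for (k in 0:(ng - 1)) mud <- mud + k * pdif[k + 1]
  dv <- 0; de <- 0
  for (k in 0:(ng - 1)) {
    dv <- dv + (k - mud)^2 * pdif[k + 1]
    de <- de - pdif[k + 1] * l2(pdif[k + 1])
  }
  hxy <- entropy; hxy1 <- 0; hxy2 <- 0; hx <- 0
  for (i in 1:ng) hx <- hx - px[i] * l2(px[i])
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - P[i, j] * l2(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  c("Cluster Shade" = shade, "Cluster Proximity" = prom,
    "Contrast" = contrast, "Correlation" = cor, "Different Entropy" = de,
    "Different Variance" = dv, "Dissimilarity" = dissim, "Energy" = energy,
    "Entropy" = entropy, "Homogeneity Normalized" = homogn,
    "Homogeneity" = homog, "InfoCorrelation1" = ic1, "InfoCorrelation2" = ic2,
    "Max Probability" = maxp, "Sum Average" = sa, "Sum Entropy" = se,
    "Sum of variance" = sv, "Variance" = varh)
}

# recursive flood fill (8-connected) + literal size-zone formulas
oracle_glszm_features <- function(q) {
  nr <- nrow(q); nc <- ncol(q)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seen[i, j]) next
    lev <- q[i, j]; size <- 0
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc &&
            !seen[ii, jj] && q[ii, jj] == lev) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev + 1, size)
  }
  g <- vapply(zones, `[`, 0, 1); s <- vapply(zones, `[`, 0, 2)
  nz <- length(zones); np <- nr * nc
  c("Small area emphasis" = sum(1 / s^2) / nz,
    "Large area emphasis" = sum(s^2) / nz,
    "Low intensity emphasis" = sum(1 / g^2) / nz,
    "High intensity emphasis" = sum(g^2) / nz,
    "Low intensity small area emphasis" = sum(1 / (g * s)^2) / nz,
    "Low intensity large area emphasis" = sum(s^2 / g^2) / nz,
    "High intensity small area emphasis" = sum(g^2 / s^2) / nz,
    "High intensity large area emphasis" = sum((g * s)^2) / nz,
    "Intensity variance" = sum((g - mean(g))^2) / nz,
    "Size zone variance" = sum((s - mean(s))^2) / nz,
    "Zone%" = nz / np)
}

# first-order statistics, recomputed directly
oracle_gray_stats <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  va <- sum((v - m)^2) / n
  h <- rep(0, 256)
  for (x in v) {
    b <- min(max(floor(x + 0.5), 0), 255) + 1
    h[b] <- h[b] + 1
  }
  p <- h / n
  ent <- 0
  for (pp in p) if (pp > 0) ent <- ent - pp * log2(pp)
  c(Mean = m, Median = median(v), Variance = va,
    `Standard deviation` = sqrt(va), `Max Pixel Value` = max(v),
    `Min Pixel Value` = min(v),
    Skewness = if (va > 1e-12) (sum((v - m)^3) / n) / va^1.5 else 0,
    Kurtosis = if (va > 1e-12) (sum((v - m)^4) / n) / va^2 else 0,
    Energy = sum(p^2), Entropy = ent, Range = max(v) - min(v))
}

# Hu moments transcribed from the eta definitions with explicit loops
oracle_hu <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  m00 <- 0; mx <- 0; my <- 0
  for (i in 1:nr) for (j in 1:nc) {
    m00 <- m00 + img[i, j]
    mx <- mx + (j - 1) * img[i, j]
    my <- my + (i - 1) * img[i, j]
  }
  xb <- mx / m00; yb <- my / m00
  mu <- function(p, q) {
    s <- 0
    for (i in 1:nr) for (j in 1:nc)
      s <- s + (j - 1 - xb)^p * (i - 1 - yb)^q * img[i, j]
    s
  }
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# all-pairs AUC with ties counted one half
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  100 * s / (length(pos) * length(neg))
}

# small helpers shared by tests
random_mask <- function(nr, nc, p = 0.6) {
  matrix(runif(nr * nc) < p, nr, nc)
}

make_ball_node <- function(r = 10, pad = 3, spacing = c(1, 1, 1), value = 100) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  mask <- array(sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) <= r,
                c(n, n, n))
  node_image(array(value, c(n, n, n)), mask, spacing, "ball")
}
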