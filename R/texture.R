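# Texture features: GLCM (18 Haralick-type statistics at 20 offsets),
# GLSZM (11), gray-level statistics (11), Hu invariant moments (7), and
# boundary-band contrast features (6 per radius).
#
# Conventions (frozen so features are comparable across nodes): gray
# values are quantized by uniform binning of the fixed display range
# [0, 255] (not per-ROI min-max); co-occurrence matrices are symmetrized
# and normalized; logarithms are base 2 with 0*log(0) = 0; GLSZM zones are
# 8-connected; intensity weights use 1-based bin indices.

#' Quantize display gray values to a fixed number of levels
#'
#' Uniform binning of the fixed \[0, 255\] range: `bin = floor(v * levels
#' / 256)`, so value 0 maps to bin 0 and 255 to `levels - 1`.
#'
#' @param patch numeric matrix of gray values in \[0, 255\].
#' @param levels number of gray levels (>= 2; the catalog uses 16).
#' @return integer matrix of bins in `0 .. levels-1`.
#' @export
quantize_gray <- function(patch, levels = 16) {
  if (length(patch) == 0) nr_stop("noderad_empty_roi", "empty patch")
  if (!is.numeric(levels) || levels < 2)
    nr_stop("noderad_parameter_error", "levels must be >= 2")
  q <- floor(patch * levels / 256)
  q[q > levels - 1] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

glcm_offset <- function(direction, distance) {
  switch(as.character(direction),
         "0" = c(0, distance),
         "45" = c(-distance, distance),
         "90" = c(-distance, 0),
         "135" = c(-distance, -distance),
         nr_stop("noderad_parameter_error", "direction must be 0/45/90/135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts gray-level pairs at the given (direction, distance)
#' displacement, adds the transpose (symmetric convention), and
#' normalizes to sum 1.
#'
#' @param q integer matrix of quantized levels `0 .. levels-1`.
#' @param direction angle in degrees, one of 0, 45, 90, 135.
#' @param distance displacement in pixels (>= 1).
#' @param levels number of gray levels.
#' @return `levels x levels` probability matrix.
#' @export
glcm <- function(q, direction, distance, levels = 16) {
  off <- glcm_offset(direction, distance)
  nr <- nrow(q); nc <- ncol(q)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rs <- rs[rs + off[1] >= 1 & rs + off[1] <= nr]
  cs <- cs[cs + off[2] >= 1 & cs + off[2] <= nc]
  if (length(rs) == 0 || length(cs) == 0)
    nr_stop("noderad_empty_pairs", "patch too small for displacement (d=%d)", distance)
  a <- q[rs, cs, drop = FALSE]
  b <- q[rs + off[1], cs + off[2], drop = FALSE]
  counts <- tabulate(a * levels + b + 1L, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

#' The 18 co-occurrence texture statistics
#'
#' Standard Haralick-style definitions on a symmetric, normalized GLCM
#' with 1-based gray-level weights: Cluster Shade, Cluster Proximity
#' (= cluster prominence), Contrast, Correlation, Different Entropy,
#' Different Variance, Dissimilarity, Energy, Entropy, Homogeneity
#' Normalized (inverse difference moment normalized), Homogeneity,
#' InfoCorrelation1/2, Max Probability, Sum Average, Sum Entropy, Sum of
#' variance (about the sum average), Variance. Logs are base 2. A
#' constant patch has zero marginal variance; Correlation is defined as 1
#' there.
#'
#' @param P symmetric probability matrix summing to 1.
#' @return named numeric vector of length 18 (catalog order).
#' @export
glcm_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8)
    nr_stop("noderad_contract_error", "GLCM must be normalized")
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(ng) * px)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)

  psum <- tapply(as.vector(P), as.vector(i + j), sum)        # k = 2..2ng
  ks <- as.numeric(names(psum))
  pdiff <- tapply(as.vector(P), as.vector(abs(i - j)), sum)  # k = 0..ng-1
  kd <- as.numeric(names(pdiff))

  sa <- sum(ks * psum)
  se <- -sum(psum * xlog2(psum))
  sv <- sum((ks - sa)^2 * psum)
  mu_d <- sum(kd * pdiff)
  dv <- sum((kd - mu_d)^2 * pdiff)
  de <- -sum(pdiff * xlog2(pdiff))

  hxy <- -sum(P * xlog2(P))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  hx <- -sum(px * xlog2(px))
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  corr <- if (var_x > 1e-12) (sum(i * j * P) - mu_x^2) / var_x else 1

  c("Cluster Shade" = sum((i + j - 2 * mu_x)^3 * P),
    "Cluster Proximity" = sum((i + j - 2 * mu_x)^4 * P),
    "Contrast" = sum((i - j)^2 * P),
    "Correlation" = corr,
    "Different Entropy" = de,
    "Different Variance" = dv,
    "Dissimilarity" = sum(abs(i - j) * P),
    "Energy" = sum(P^2),
    "Entropy" = hxy,
    "Homogeneity Normalized" = sum(P / (1 + (i - j)^2 / ng^2)),
    "Homogeneity" = sum(P / (1 + (i - j)^2)),
    "InfoCorrelation1" = ic1,
    "InfoCorrelation2" = ic2,
    "Max Probability" = max(P),
    "Sum Average" = sa,
    "Sum Entropy" = se,
    "Sum of variance" = sv,
    "Variance" = sum((i - mu_x)^2 * P))
}

#' The 11 gray-level size-zone features
#'
#' Zones are 8-connected regions of constant quantized level; intensity
#' weights use the 1-based bin index g, size weights the zone pixel count
#' s. With N_z zones and N_p pixels: small/large area emphasis are the
#' N_z-normalized sums of 1/s^2 and s^2, the intensity emphases use 1/g^2
#' and g^2, the four combinations cross both, the variances are the
#' zone-weighted variances of g and s, and Zone% = N_z / N_p.
#'
#' @param q integer matrix of quantized levels `0 .. levels-1`.
#' @return named numeric vector of length 11 (catalog order).
#' @export
glszm_features <- function(q) {
  if (length(q) == 0) nr_stop("noderad_empty_roi", "empty patch")
  z <- cpp_zones(q, TRUE)
  g <- z[, 1] + 1
  s <- z[, 2]
  nz <- nrow(z)
  np <- length(q)
  mg <- mean(g); ms <- mean(s)
  c("Small area emphasis" = mean(1 / s^2),
    "Large area emphasis" = mean(s^2),
    "Low intensity emphasis" = mean(1 / g^2),
    "High intensity emphasis" = mean(g^2),
    "Low intensity small area emphasis" = mean(1 / (g^2 * s^2)),
    "Low intensity large area emphasis" = mean(s^2 / g^2),
    "High intensity small area emphasis" = mean(g^2 / s^2),
    "High intensity large area emphasis" = mean(g^2 * s^2),
    "Intensity variance" = mean((g - mg)^2),
    "Size zone variance" = mean((s - ms)^2),
    "Zone%" = nz / np)
}

#' The 11 first-order gray-level statistics
#'
#' Mean, median, population variance and standard deviation, max, min,
#' skewness and kurtosis (population moment ratios; 0 for constant
#' input), energy and entropy of the 256-bin value histogram, and range.
#'
#' @param values numeric vector of gray values (masked pixels), nonempty.
#' @return named numeric vector of length 11 (catalog order).
#' @export
gray_level_features <- function(values) {
  if (length(values) == 0) nr_stop("noderad_empty_roi", "no masked pixels")
  m <- mean(values)
  v <- pop_var(values)
  s <- sqrt(v)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  h <- tabulate(pmin(pmax(round_half_up(values), 0), 255) + 1L, nbins = 256)
  p <- h / sum(h)
  c("Mean" = m,
    "Median" = median(values),
    "Variance" = v,
    "Standard deviation" = s,
    "Max Pixel Value" = max(values),
    "Min Pixel Value" = min(values),
    "Skewness" = if (v > 1e-12) m3 / s^3 else 0,
    "Kurtosis" = if (v > 1e-12) m4 / v^2 else 0,
    "Energy" = sum(p^2),
    "Entropy" = -sum(p * xlog2(p)),
    "Range" = max(values) - min(values))
}

#' The seven Hu invariant moments
#'
#' Computed from normalized central moments of the gray image treated as
#' a density; invariant to translation, scale, and rotation.
#'
#' @param patch numeric matrix with nonzero total intensity.
#' @return named numeric vector `Hu moment 1` .. `Hu moment 7`.
#' @export
invariant_moments <- function(patch) {
  m00 <- sum(patch)
  if (!is.finite(m00) || m00 <= 0)
    nr_stop("noderad_degenerate_moments", "patch has zero total intensity")
  nr <- nrow(patch); nc <- ncol(patch)
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr) - 1, nr, nc)
  xb <- sum(x * patch) / m00
  yb <- sum(y * patch) / m00
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q * patch)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  setNames(c(h1, h2, h3, h4, h5, h6, h7), paste("Hu moment", 1:7))
}

#' The six boundary-contrast features for one band radius
#'
#' Mean and population SD of gray values over the inside and outside
#' boundary bands, plus the inside-minus-outside differences of both. A
#' band that is empty (node at the image border) contributes imputed
#' zeros with a warning rather than an error.
#'
#' @param image numeric matrix of section gray values.
#' @param bands list with logical matrices `inside` and `outside`
#'   (from [boundary_bands()]).
#' @return named numeric vector of length 6.
#' @export
edge_features <- function(image, bands) {
  stat <- function(m, what) {
    v <- image[m]
    if (length(v) == 0) {
      nr_warn("empty %s boundary band: imputing 0", what)
      return(c(0, 0))
    }
    c(mean(v), pop_sd(v))
  }
  ins <- stat(bands$inside, "inside")
  out <- stat(bands$outside, "outside")
  c("Mean inside" = ins[1], "Mean outside" = out[1],
    "SD inside" = ins[2], "SD outside" = out[2],
    "Mean difference" = ins[1] - out[1],
    "SD difference" = ins[2] - out[2])
}
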