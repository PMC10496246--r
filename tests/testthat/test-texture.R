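# texture_features: quantization, GLCM, GLSZM, gray-level statistics,
# Hu moments, boundary-contrast features

test_that("quantization bins the fixed [0,255] range uniformly", {
  expect_equal(quantize_gray(matrix(0, 1, 1))[1, 1], 0L)
  expect_equal(quantize_gray(matrix(255, 1, 1))[1, 1], 15L)
  expect_equal(quantize_gray(matrix(16, 1, 1))[1, 1], 1L)  # 16*16/256 = 1
  expect_equal(quantize_gray(matrix(15.9, 1, 1))[1, 1], 0L)
  q <- quantize_gray(matrix(128, 4, 4))
  expect_equal(length(unique(as.vector(q))), 1)
  expect_error(quantize_gray(matrix(1, 2, 2), levels = 1),
               class = "noderad_parameter_error")
})

test_that("glcm handles constant and stripe patches per closed form", {
  qc <- matrix(3L, 5, 5)
  P <- glcm(qc, 0, 1)
  expect_equal(P[4, 4], 1)
  expect_equal(sum(P), 1)

  qs <- matrix(rep(c(0L, 1L), 10), 4, 5, byrow = TRUE)  # 0,1,0,1 stripes
  P <- glcm(qs, 0, 1)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)

  expect_error(glcm(matrix(0L, 2, 2), 0, 5), class = "noderad_empty_pairs")
})

test_that("glcm equals the brute-force pair-counting oracle on all 20 configs", {
  set.seed(21)
  for (rep in 1:5) {
    q <- matrix(sample(0:15, 36, replace = TRUE), 6, 6)
    for (d in 1:5) for (a in c(0, 45, 90, 135)) {
      if (d >= 6) next
      expect_equal(glcm(q, a, d), oracle_glcm(q, a, d), tolerance = 1e-12)
    }
  }
})

test_that("glcm matrices are symmetric probability distributions", {
  set.seed(22)
  for (rep in 1:10) {
    q <- matrix(sample(0:15, 64, replace = TRUE), 8, 8)
    P <- glcm(q, sample(c(0, 45, 90, 135), 1), sample(1:5, 1))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
  }
})

test_that("glcm_features: analytic limits and the literal-formula oracle", {
  # constant patch
  f <- glcm_features(glcm(matrix(7L, 6, 6), 0, 1))
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Homogeneity"]), 1)
  expect_equal(unname(f["Max Probability"]), 1)

  # two-entry stripe GLCM: contrast 1, energy 0.5, entropy 1 bit
  f <- glcm_features(glcm(matrix(rep(c(0L, 1L), 12), 4, 6, byrow = TRUE), 0, 1))
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["Energy"]), 0.5)
  expect_equal(unname(f["Entropy"]), 1)

  set.seed(23)
  for (rep in 1:20) {
    q <- matrix(sample(0:15, 64, replace = TRUE), 8, 8)
    P <- glcm(q, sample(c(0, 45, 90, 135), 1), sample(1:3, 1))
    expect_equal(glcm_features(P), oracle_glcm_features(P), tolerance = 1e-9)
  }

  expect_error(glcm_features(matrix(1, 16, 16)),
               class = "noderad_contract_error")
})

test_that("glszm_features: closed forms and the flood-fill oracle", {
  # constant patch: one zone of N pixels
  qc <- matrix(5L, 4, 6)
  f <- glszm_features(qc)
  expect_equal(unname(f["Zone%"]), 1 / 24)
  expect_equal(unname(f["Small area emphasis"]), 1 / 24^2)
  expect_equal(unname(f["Large area emphasis"]), 24^2)

  # four-level tiling where all 8-neighbors differ: every zone is a
  # single pixel (a two-level checkerboard would join diagonals)
  qb <- outer(1:5, 1:5, function(i, j) (i %% 2L) * 2L + (j %% 2L))
  f <- glszm_features(qb)
  expect_equal(unname(f["Small area emphasis"]), 1)
  expect_equal(unname(f["Zone%"]), 1)

  set.seed(24)
  for (rep in 1:15) {
    q <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
    expect_equal(glszm_features(q), oracle_glszm_features(q),
                 tolerance = 1e-9)
  }
})

test_that("gray_level_features: closed forms and the statistics oracle", {
  f <- gray_level_features(rep(42, 50))
  expect_equal(unname(f[c("Mean", "Median", "Variance", "Energy",
                          "Entropy", "Range")]),
               c(42, 42, 0, 1, 0, 0))

  f <- gray_level_features(rep(c(0, 255), 20))
  expect_equal(unname(f["Mean"]), 127.5)
  expect_equal(unname(f["Entropy"]), 1)

  set.seed(25)
  for (rep in 1:15) {
    v <- runif(sample(20:200, 1), 0, 255)
    expect_equal(gray_level_features(v), oracle_gray_stats(v),
                 tolerance = 1e-9)
  }
  expect_error(gray_level_features(numeric(0)), class = "noderad_empty_roi")
})

test_that("Hu moments: invariances and transcription oracle", {
  set.seed(26)
  patch <- matrix(runif(121, 0, 255), 11, 11)

  # rotation by 90 degrees
  expect_equal(invariant_moments(patch),
               invariant_moments(t(patch[nrow(patch):1, ])),
               tolerance = 1e-9, ignore_attr = TRUE)

  # 2x nearest-neighbor upscaling (discretization-limited tolerance)
  big <- patch[rep(1:11, each = 2), rep(1:11, each = 2)]
  expect_equal(invariant_moments(patch), invariant_moments(big),
               tolerance = 1e-3, ignore_attr = TRUE)

  # high-resolution rasterized disc vs direct numerical integration
  n <- 101
  xy <- expand.grid(r = 1:n, c = 1:n)
  disc <- matrix(as.numeric((xy$r - 51)^2 + (xy$c - 51)^2 <= 40^2), n, n)
  expect_equal(unname(invariant_moments(disc)), oracle_hu(disc),
               tolerance = 1e-9)
  # analytic check: hu1 of an ideal disc is 1/(2*pi)
  expect_equal(unname(invariant_moments(disc)[1]), 1 / (2 * pi),
               tolerance = 1e-3)

  for (rep in 1:10) {
    p <- matrix(runif(81, 0, 10), 9, 9)
    expect_equal(unname(invariant_moments(p)), oracle_hu(p),
                 tolerance = 1e-9)
  }
  expect_error(invariant_moments(matrix(0, 4, 4)),
               class = "noderad_degenerate_moments")
})

test_that("edge_features: uniform bands, symmetric texture, empty band", {
  img <- matrix(50, 20, 20); img[6:15, 6:15] <- 200
  mask <- matrix(FALSE, 20, 20); mask[6:15, 6:15] <- TRUE
  b <- boundary_bands(mask, 3)
  f <- edge_features(img, b)
  expect_equal(unname(f), c(200, 50, 0, 0, 150, 0))

  set.seed(27)
  img2 <- matrix(runif(400, 0, 255), 20, 20)
  f2 <- edge_features(img2, b)
  expect_lt(abs(f2[["Mean difference"]]), 30)  # same texture both sides

  full <- matrix(TRUE, 10, 10)  # no outside pixels at all
  expect_warning(f3 <- edge_features(matrix(1, 10, 10),
                                     boundary_bands(full, 3)),
                 "empty outside")
  expect_equal(unname(f3["Mean outside"]), 0)
})

test_that("boundary blur shrinks the edge contrast (ENE signature)", {
  sharp <- phantom_spec(blur_mm = c(normal = 0.2, metastatic = 0.2, ENE = 0.2))
  blurred <- phantom_spec(blur_mm = c(normal = 2.0, metastatic = 2.0, ENE = 2.0))
  diff_of <- function(spec, seed) {
    nd <- generate_node(spec, "metastatic", seed = seed)
    geom <- section_geometry(nd)
    edge_features(geom$section_image,
                  geom$boundary_bands$r5)[["Mean difference"]]
  }
  for (s in 1:3)
    expect_lt(abs(diff_of(blurred, s)), abs(diff_of(sharp, s)))
})

test_that("texture features ignore mask translation and node identity", {
  set.seed(28)
  q <- matrix(sample(0:15, 49, replace = TRUE), 7, 7)
  pad1 <- matrix(0L, 12, 12); pad1[1:7, 1:7] <- q
  pad2 <- matrix(0L, 12, 12); pad2[6:12, 6:12] <- q
  # same patch content extracted from different positions
  expect_identical(glcm_features(glcm(pad1[1:7, 1:7], 45, 2)),
                   glcm_features(glcm(pad2[6:12, 6:12], 45, 2)))
  expect_identical(glszm_features(pad1[1:7, 1:7]),
                   glszm_features(pad2[6:12, 6:12]))
})
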