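# morphology_features: 24 section-shape and 29 3D-shape features

test_that("shape2d: solid square, rasterized disc, hull monotonicity", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  f <- shape2d(sq)
  expect_length(f, 24)
  expect_equal(unname(f["Area"]), 100)
  expect_equal(unname(f["Solidity"]), 1)
  expect_equal(unname(f["Extent"]), 1)
  expect_equal(unname(f["Bounding Box Area"]), 100)

  g <- expand.grid(r = 1:71, c = 1:71)
  disc <- matrix((g$r - 36)^2 + (g$c - 36)^2 <= 30^2, 71, 71)
  f <- shape2d(disc)
  expect_lt(abs(f[["Compactness"]] - 1), 0.05)
  expect_lt(abs(f[["Roundness"]] - 1), 0.05)
  expect_lt(abs(f[["Eccentricity"]]), 0.1)
  expect_lt(abs(f[["Equivalent Diameter"]] - 60), 1)

  bitten <- sq; bitten[6:9, 3:7] <- FALSE  # bite into one side
  f2 <- shape2d(bitten)
  expect_lt(f2[["Solidity"]], f[["Solidity"]] * 0 + 1)
  expect_lt(f2[["Solidity"]], shape2d(sq)[["Solidity"]])

  expect_error(shape2d(matrix(FALSE, 3, 3)), class = "noderad_empty_roi")
})

test_that("shape2d axes follow the second-moment ellipse", {
  g <- expand.grid(r = 1:61, c = 1:101)
  ell <- matrix(((g$r - 31) / 15)^2 + ((g$c - 51) / 40)^2 <= 1, 61, 101)
  f <- shape2d(ell)
  expect_lt(abs(f[["Major Axis Length"]] - 80) / 80, 0.03)
  expect_lt(abs(f[["Minor Axis Length"]] - 30) / 30, 0.03)
  expect_lt(abs(f[["Orientation"]]), 2)  # angle vs the column axis: 0 here
  expect_lt(abs(f[["Eccentricity"]] - sqrt(1 - (15 / 40)^2)), 0.02)
  expect_lt(abs(f[["Aspect Ratio"]] - 8 / 3), 0.1)
})

test_that("shape3d on a digital ball matches analytic values", {
  m3 <- build_3d_node(make_ball_node(r = 10))
  f <- shape3d(m3)
  expect_length(f, 29)
  expect_gt(f[["Solidity"]], 0.98)
  expect_lt(abs(f[["Compactness"]] - 1), 0.1)
  expect_lt(abs(f[["Gaussian Curvature sum"]] - 4 * pi) / (4 * pi), 0.05)
  expect_lt(abs(f[["Mean Curvature sum"]] - 4 * pi * 10) / (4 * pi * 10), 0.1)
  expect_lt(abs(f[["Volume"]] - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_lt(abs(f[["Surface"]] - 4 * pi * 100) / (4 * pi * 100), 0.1)
  expect_lt(abs(f[["Equivalent diameter"]] - 20) / 20, 0.05)
  expect_lt(abs(f[["Principal Axis Length 1"]] - 20) / 20, 0.1)
  expect_lt(abs(f[["Roundness"]] - 1), 0.1)
})

test_that("ellipsoid vs ball: elongation and eccentricity ordering", {
  n <- 41; ctr <- 21
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 8^2, c(n, n, n))
  ell <- array(((g$x - ctr) / 8)^2 + ((g$y - ctr) / 8)^2 +
                 ((g$z - ctr) / 16)^2 <= 1, c(n, n, n))
  fb <- shape3d(build_3d_node(node_image(array(1, dim(ball)), ball, c(1, 1, 1))))
  fe <- shape3d(build_3d_node(node_image(array(1, dim(ell)), ell, c(1, 1, 1))))
  expect_gt(fe[["Elongation"]], fb[["Elongation"]])
  expect_gt(fe[["Eccentricity"]], fb[["Eccentricity"]])
  expect_lt(abs(fe[["Aspect radius 2"]] - 2), 0.2)  # axes (2, 1, 1)
})

test_that("surface spikes lower solidity but barely move the convex hull", {
  # build raw arrays first: node_image trims empty slices, so the spikes
  # must exist before construction
  n <- 29; ctr <- 15
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array(sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) <= 9,
                c(n, n, n))
  spiky <- ball
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    for (t in 0:12) {
      p <- ctr + s * t
      spiky[p[1], p[2], p[3]] <- TRUE
    }
  }
  vol <- array(100, c(n, n, n))
  f0 <- shape3d(build_3d_node(node_image(vol, ball, c(1, 1, 1), "ball")))
  f1 <- shape3d(build_3d_node(node_image(vol, spiky, c(1, 1, 1), "spiky")))
  expect_lt(f1[["Solidity"]], f0[["Solidity"]])
  expect_lt(abs(f1[["Convex volume"]] - f0[["Convex volume"]]) /
              f0[["Convex volume"]], 0.25)
})

test_that("3D features are invariant to axis relabeling (up to orientation)", {
  nd <- generate_node(phantom_spec(spacing = c(1, 1, 1),
                                   axes_mm = c(6, 9), axis_z_mm = c(6, 9)),
                      "metastatic", seed = 4)
  f1 <- shape3d(build_3d_node(nd))
  perm <- aperm(nd$mask, c(2, 3, 1))
  nd2 <- node_image(aperm(nd$volume, c(2, 3, 1)), perm, c(1, 1, 1), "perm")
  f2 <- shape3d(build_3d_node(nd2))
  keep <- setdiff(names(f1), c("Orientation1", "Orientation2", "Orientation3"))
  expect_equal(f1[keep], f2[keep], tolerance = 0.05)
})

test_that("Gauss-Bonnet holds on phantom meshes of all classes", {
  spec <- phantom_spec()
  for (cl in node_classes()) {
    m3 <- build_3d_node(generate_node(spec, cl, seed = 31))
    expect_true(mesh_topology(m3$vertices, m3$faces)$closed)
    gc_sum <- gaussian_curvature_total(m3$vertices, m3$faces)
    expect_lt(abs(gc_sum - 4 * pi) / (4 * pi), 0.05)
  }
})
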