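# 3D morphology of the isotropic node model (29 features).
#
# Conventions: Volume is voxel count x voxel volume; Surface is the
# smoothed-mesh area; principal axes come from the voxel inertia
# (covariance) tensor with the 1/12 unit-voxel correction, reported as
# full solid-ellipsoid axis lengths 2*sqrt(5*lambda) in descending
# order; orientations are ZYX Euler angles of the eigenvector frame;
# convex quantities use the 3D hull of voxel corners (so Solidity stays
# in (0, 1]); curvature sums are the discrete angle-defect total
# (Gauss-Bonnet: ~4*pi for genus 0) and the Steiner edge-based total
# mean curvature (~4*pi*R for a ball of radius R).

#' The 29 node-shape features from the 3D model
#'
#' @param model a `node_model3d` from [build_3d_node()].
#' @return named numeric vector of length 29 (catalog order); lengths in
#'   mm, areas mm^2, volumes mm^3.
#' @export
shape3d <- function(model) {
  if (!inherits(model, "node_model3d"))
    nr_stop("noderad_input_error", "model must come from build_3d_node()")
  sp <- model$spacing
  vox <- which(model$mask, arr.ind = TRUE)
  nvox <- nrow(vox)
  if (nvox < 8) nr_stop("noderad_degenerate_3d", "too few voxels for 3D shape")
  volume <- nvox * sp^3
  surface <- mesh_area(model$vertices, model$faces)

  ctr <- colMeans(vox)
  cc <- sweep(vox, 2, ctr)
  covm <- crossprod(cc) / nvox + diag(1 / 12, 3)
  ev <- eigen(covm, symmetric = TRUE)
  lam <- ev$values                     # descending
  axlen <- 2 * sqrt(5 * lam) * sp      # solid ellipsoid: var = a^2/5
  R <- ev$vectors
  # deterministic sign convention, then right-handedness
  for (k in 1:3) {
    nz <- which(abs(R[, k]) > 1e-12)[1]
    if (R[nz, k] < 0) R[, k] <- -R[, k]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  eul <- euler_zyx(R)

  # convex hull over surface-voxel centers; the voxel-count volume and
  # the center hull carry opposite-signed half-voxel biases, so the hull
  # volume is floored at Volume to keep Solidity in (0, 1]
  shell <- model$mask & !erode3(model$mask)
  svox <- which(shell, arr.ind = TRUE)
  hull <- cpp_convex_hull3(svox * sp)
  cvol <- max(hull$volume, volume)
  csurf <- hull$area

  bbox <- prod(apply(vox, 2, function(v) diff(range(v)) + 1)) * sp^3
  maxrad <- max(sqrt(rowSums(sweep(model$vertices, 2, ctr * sp)^2)))
  gc_sum <- gaussian_curvature_total(model$vertices, model$faces)
  mc_sum <- mean_curvature_total(model$vertices, model$faces)

  c("Volume" = volume,
    "Surface" = surface,
    "Equivalent diameter" = (6 * volume / pi)^(1 / 3),
    "Extent" = volume / bbox,
    "Principal Axis Length 1" = axlen[1],
    "Principal Axis Length 2" = axlen[2],
    "Principal Axis Length 3" = axlen[3],
    "Orientation1" = eul[1],
    "Orientation2" = eul[2],
    "Orientation3" = eul[3],
    "Eccentricity" = sqrt(max(0, 1 - lam[3] / lam[1])),
    "Solidity" = volume / cvol,
    "Convex volume" = cvol,
    "Convex surface" = csurf,
    "Convexity" = csurf / surface,
    "Compactness" = 36 * pi * volume^2 / surface^3,
    "Rectangularity" = volume / (axlen[1] * axlen[2] * axlen[3]),
    "Elongation" = 1 - axlen[2] / axlen[1],
    "Roundness" = (6 * volume / pi)^(1 / 3) / axlen[1],
    "Area volume ratio" = surface / volume,
    "Aspect radius 1" = axlen[1] / axlen[2],
    "Aspect radius 2" = axlen[1] / axlen[3],
    "Aspect radius 3" = axlen[2] / axlen[3],
    "Max radius" = maxrad,
    "Bounding box volume" = bbox,
    "Ellipticity" = volume / (pi / 6 * axlen[1] * axlen[2] * axlen[3]),
    "Defect ratio" = (cvol - volume) / cvol,
    "Gaussian Curvature sum" = gc_sum,
    "Mean Curvature sum" = mc_sum)
}

# 6-neighborhood erosion of a 3D logical array (shell extraction)
erode3 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift3 <- function(m, ax, by) {
    o <- array(FALSE, dim(m))
    idx_src <- lapply(dim(m), seq_len)
    idx_dst <- idx_src
    n <- dim(m)[ax]
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    o[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    o
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out & shift3(mask, ax, by)
  out
}

# ZYX Euler angles (degrees) of a rotation matrix
euler_zyx <- function(R) {
  sy <- -R[3, 1]
  sy <- pmin(pmax(sy, -1), 1)
  theta_y <- asin(sy)
  if (abs(abs(sy) - 1) > 1e-9) {
    theta_z <- atan2(R[2, 1], R[1, 1])
    theta_x <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock
    theta_z <- atan2(-R[1, 2], R[2, 2])
    theta_x <- 0
  }
  c(theta_z, theta_y, theta_x) * 180 / pi
}
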