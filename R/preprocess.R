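# Image pre-processing: CT windowing, contour rasterization, mask
# refinement, and the geometric primitives every extractor consumes.

#' Construct a per-node CT volume
#'
#' Bundles a normalized gray-value volume, its binary mask, and voxel
#' spacing for one lymph node. Slices without any mask voxel are trimmed
#' from both ends so every retained slice carries part of the node.
#'
#' @param volume numeric array (rows x cols x slices) with values in
#'   \[0, 255\] (display-normalized gray values).
#' @param mask logical/numeric array of the same shape; nonzero = node.
#' @param spacing numeric length-3, mm per voxel: in-plane row, in-plane
#'   column, slice.
#' @param node_id character identifier.
#' @param label optional class label, one of `"normal"`, `"metastatic"`,
#'   `"ENE"` (absent at prediction time).
#' @return an object of class `node_image`.
#' @export
node_image <- function(volume, mask, spacing, node_id = "node", label = NULL) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    nr_stop("noderad_input_error", "volume must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(volume), dim(mask)))
    nr_stop("noderad_input_error", "volume and mask shapes differ")
  if (any(volume < 0 | volume > 255))
    nr_stop("noderad_input_error", "volume values must lie in [0, 255]")
  if (length(spacing) != 3L || any(spacing <= 0))
    nr_stop("noderad_input_error", "spacing must be 3 positive mm values")
  if (!any(mask)) nr_stop("noderad_empty_roi", "mask is empty")
  if (!is.null(label)) label <- match.arg(label, node_classes())

  keep <- which(apply(mask, 3, any))
  rng <- min(keep):max(keep)
  volume <- volume[, , rng, drop = FALSE]
  mask <- mask[, , rng, drop = FALSE]
  if (!all(apply(mask, 3, any)))
    nr_stop("noderad_input_error",
            "mask has interior slices with no voxels (split node?)")
  structure(list(volume = volume, mask = mask,
                 spacing = as.numeric(spacing),
                 node_id = as.character(node_id), label = label),
            class = "node_image")
}

#' @export
print.node_image <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<node_image %s> %dx%dx%d voxels, spacing %.3f/%.3f/%.3f mm, %d mask voxels%s\n",
              x$node_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2],
              x$spacing[3], sum(x$mask),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Class labels in severity order
#' @return character vector `c("normal", "metastatic", "ENE")`.
#' @export
node_classes <- function() c("normal", "metastatic", "ENE")

#' Window/normalize a raw CT slice to display gray values
#'
#' Converts stored pixel values to Hounsfield units with the DICOM rescale
#' relation `HU = pixel * slope + intercept`, then maps the window
#' `[WC - WW/2, WC + WW/2]` linearly onto \[0, 255\], clipping outside and
#' rounding half-up to integers.
#'
#' @param slice a list with fields `pixel_array` (integer matrix),
#'   `rescale_slope`, `rescale_intercept`, `window_center`, `window_width`.
#' @return integer-valued matrix in \[0, 255\], same shape as the input.
#' @export
normalize_slice <- function(slice) {
  ww <- slice$window_width
  if (is.null(ww) || !is.finite(ww) || ww <= 0)
    nr_stop("noderad_invalid_metadata", "window width must be positive")
  hu <- slice$pixel_array * slice$rescale_slope + slice$rescale_intercept
  v <- (hu - (slice$window_center - ww / 2)) / ww
  v <- pmin(pmax(v, 0), 1)
  out <- round_half_up(v * 255)
  dim(out) <- dim(slice$pixel_array)
  out
}

#' Rasterize a closed planar contour onto a pixel grid
#'
#' A pixel is set iff its center lies inside the polygon under the
#' even-odd rule. Contour vertices are given in patient coordinates (mm)
#' and mapped to the grid through the slice origin and pixel spacing:
#' pixel (r, c), 1-based, has center `origin + (c-1, r-1) * spacing`.
#'
#' @param polygon numeric n x 2 matrix of (x, y) vertices in mm; the
#'   polygon is closed implicitly (last vertex joins the first).
#' @param dim integer length-2 grid size (rows, cols).
#' @param origin numeric length-2, mm position (x, y) of pixel (1, 1).
#' @param spacing numeric length-2, mm per pixel (x = column step,
#'   y = row step).
#' @return logical matrix of shape `dim`.
#' @export
rasterize_contour <- function(polygon, dim, origin = c(0, 0), spacing = c(1, 1)) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    nr_stop("noderad_contour_error", "polygon needs >= 3 vertices")
  if (anyDuplicated(polygon) && nrow(unique(polygon)) < 3L)
    nr_stop("noderad_contour_error", "degenerate polygon")
  if (polygon_self_intersects(polygon))
    nr_stop("noderad_contour_error", "self-intersecting polygon")

  nr <- dim[1]; nc <- dim[2]
  cx <- origin[1] + (seq_len(nc) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(nr) - 1) * spacing[2]
  px <- matrix(cx, nr, nc, byrow = TRUE)
  py <- matrix(cy, nr, nc)

  inside <- matrix(FALSE, nr, nc)
  n <- nrow(polygon)
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# segment-pair intersection test (proper crossings only)
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

# ---------------------------------------------------------------------------
# binary morphology (disc structuring elements)

disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

shift_mask <- function(mask, dr, dc, fill = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- mask[rs - dr, cs - dc, drop = FALSE]
  out
}

binary_dilate <- function(mask, radius) {
  off <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[k], off$dc[k], fill = FALSE)
  out
}

binary_erode <- function(mask, radius) {
  off <- disc_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off$dr[k], off$dc[k], fill = FALSE)
  out
}

#' Fill interior holes of a binary mask
#'
#' Background pixels not reachable from the image border through
#' 4-connected background are switched on.
#'
#' @param mask logical matrix.
#' @return logical matrix with no interior holes.
#' @export
fill_holes <- function(mask) {
  mask <- mask != 0
  comp <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- comp[1, ]; reach[nrow(mask), ] <- comp[nrow(mask), ]
  reach[, 1] <- comp[, 1]; reach[, ncol(mask)] <- comp[, ncol(mask)]
  repeat {
    grown <- reach |
      shift_mask(reach, 1, 0) | shift_mask(reach, -1, 0) |
      shift_mask(reach, 0, 1) | shift_mask(reach, 0, -1)
    grown <- grown & comp
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (comp & !reach)
}

#' Refine a contour mask by dilation, hole filling, and erosion
#'
#' Closes small contour gaps and removes interior holes while preserving
#' the outer boundary up to smoothing: dilate with a disc, fill holes,
#' erode with the same disc. The image is padded by the disc radius so
#' border-adjacent masks are not clipped by the intermediate dilation.
#'
#' @param mask logical matrix, nonempty.
#' @param radius disc radius in pixels (default 2; large enough to close
#'   1-2 pixel contour gaps, small enough to preserve node shape).
#' @return logical matrix, hole-free, same shape as input.
#' @export
refine_mask <- function(mask, radius = 2) {
  mask <- mask != 0
  if (!any(mask)) nr_stop("noderad_empty_roi", "empty mask")
  r <- ceiling(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2 * r, nc + 2 * r)
  pad[r + seq_len(nr), r + seq_len(nc)] <- mask
  out <- binary_erode(fill_holes(binary_dilate(pad, radius)), radius)
  out[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
}

#' Largest axis-aligned square inscribed in a mask
#'
#' Dynamic-programming construction; ties are broken by the smallest
#' (row, col) of the top-left corner, lexicographically.
#'
#' @param mask logical matrix, nonempty.
#' @return list with `row`, `col` (1-based top-left corner) and `side`.
#' @export
largest_inscribed_square <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) nr_stop("noderad_empty_roi", "empty mask")
  res <- cpp_inscribed_square(m)
  list(row = res[1], col = res[2], side = res[3])
}

#' Inside and outside boundary bands of a mask
#'
#' `outside = dilate(mask, disc(radius)) \ mask` and
#' `inside = mask \ erode(mask, disc(radius))`; the bands are disjoint and
#' are clipped to the image extent.
#'
#' @param mask logical matrix, nonempty.
#' @param radius disc radius in pixels (> 0); the boundary features use
#'   3, 5, and 10.
#' @return list with logical matrices `inside` and `outside`.
#' @export
boundary_bands <- function(mask, radius) {
  if (length(radius) != 1 || !is.finite(radius) || radius <= 0)
    nr_stop("noderad_parameter_error", "radius must be a positive number")
  mask <- mask != 0
  if (!any(mask)) nr_stop("noderad_empty_roi", "empty mask")
  list(inside = mask & !binary_erode(mask, radius),
       outside = binary_dilate(mask, radius) & !mask)
}

#' Index of the largest mask section
#'
#' The slice with the most mask pixels; ties go to the lower slice index.
#'
#' @param node a [node_image()].
#' @return integer slice index.
#' @export
largest_section <- function(node) {
  counts <- apply(node$mask, 3, sum)
  which.max(counts)  # which.max returns the first (lowest) maximum
}

#' Geometric primitives of the largest node section
#'
#' Locates the largest section, its inscribed square, and the inside and
#' outside boundary bands at the requested radii.
#'
#' @param node a [node_image()].
#' @param radii disc radii (pixels) for the boundary bands.
#' @return an object of class `section_geometry`: fields
#'   `largest_section_index`, `section_mask`, `section_image`,
#'   `inscribed_square` and `boundary_bands` (one `(inside, outside)` pair
#'   per radius).
#' @export
section_geometry <- function(node, radii = c(3, 5, 10)) {
  idx <- largest_section(node)
  m <- node$mask[, , idx]
  img <- node$volume[, , idx]
  sq <- largest_inscribed_square(m)
  bands <- lapply(radii, function(r) boundary_bands(m, r))
  names(bands) <- paste0("r", radii)
  structure(list(largest_section_index = idx, section_mask = m,
                 section_image = img, inscribed_square = sq,
                 boundary_bands = bands, radii = radii),
            class = "section_geometry")
}

#' Extract the inscribed-square gray patch of the largest section
#' @param node a [node_image()].
#' @param geom optional precomputed [section_geometry()].
#' @return numeric matrix (side x side) of gray values.
#' @export
inscribed_patch <- function(node, geom = section_geometry(node)) {
  sq <- geom$inscribed_square
  geom$section_image[sq$row + seq_len(sq$side) - 1,
                     sq$col + seq_len(sq$side) - 1, drop = FALSE]
}

# signed distance (pixels) to the mask's inner boundary layer: positive
# inside, negative outside; used for shape-based z interpolation
signed_distance2d <- function(mask) {
  mask <- mask != 0
  nrw <- nrow(mask); ncl <- ncol(mask)
  bnd <- mask & !binary_erode(mask, 1)
  bp <- which(bnd, arr.ind = TRUE)
  pr <- matrix(seq_len(nrw), nrw, ncl)
  pc <- matrix(seq_len(ncl), nrw, ncl, byrow = TRUE)
  d2 <- matrix(Inf, nrw, ncl)
  for (i in seq_len(nrow(bp)))
    d2 <- pmin(d2, (pr - bp[i, 1])^2 + (pc - bp[i, 2])^2)
  d <- sqrt(d2)
  # half-pixel offset: the region edge lies half a pixel outside the
  # innermost boundary-pixel centers, so the interpolated zero-level
  # tracks the pixel edge instead of shrinking by ~0.5 px per slice
  ifelse(mask, d + 0.5, 0.5 - d)
}

# Catmull-Rom interpolation along the slice axis of a (rows, cols,
# slices) array; output slice o (0-based) sits at input slice coordinate
# o * step_z. Curvature-following, so interpolated cross-sections of
# round shapes do not collapse to conical frustums like linear
# interpolation does.
resample_z_catmull <- function(arr, step_z, nz_out) {
  d <- dim(arr)
  out <- array(0, c(d[1], d[2], nz_out))
  get <- function(k) arr[, , min(max(k, 1L), d[3])]
  for (o in seq_len(nz_out)) {
    zf <- (o - 1) * step_z
    k <- floor(zf)
    t <- zf - k
    p1 <- get(k + 1L); p2 <- get(k + 2L)
    if (t < 1e-12) { out[, , o] <- p1; next }
    p0 <- get(k); p3 <- get(k + 3L)
    out[, , o] <- 0.5 * ((2 * p1) + (p2 - p0) * t +
                         (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
                         (3 * p1 - p0 - 3 * p2 + p3) * t^3)
  }
  out
}

# ---------------------------------------------------------------------------
# isotropic 3D model

#' Build the isotropic 3D node model and its surface mesh
#'
#' Stacks the node's slices, corrects the physical height using the
#' in-plane pixel size and slice thickness (e.g. 0.468 mm pixels, 3 mm
#' slices), trilinearly resamples mask and volume to isotropic voxels at
#' the in-plane resolution, extracts a closed triangulated surface
#' (marching tetrahedra on a lightly blurred indicator field), and applies
#' one Laplacian smoothing pass. The mesh is watertight by construction.
#'
#' @param node a [node_image()] with at least two mask-bearing slices and
#'   equal in-plane spacing.
#' @return an object of class `node_model3d`: `mask` (isotropic logical
#'   array), `volume` (isotropic gray array), `spacing` (scalar mm),
#'   `vertices` (n x 3, mm), `faces` (m x 3, 1-based).
#' @export
build_3d_node <- function(node) {
  d <- dim(node$mask)
  if (d[3] < 2L)
    nr_stop("noderad_degenerate_3d",
            "single-slice node: no 3D model (2D features remain computable)")
  sp <- node$spacing
  if (abs(sp[1] - sp[2]) > 1e-9)
    nr_stop("noderad_input_error", "anisotropic in-plane spacing unsupported")
  s_in <- sp[1]
  nz_out <- floor((d[3] - 1) * sp[3] / s_in) + 1
  outdim <- c(d[1], d[2], as.integer(nz_out))
  step <- c(1, 1, s_in / sp[3])

  # Thresholded trilinear interpolation of a binary indicator reduces to
  # nearest-neighbor along z (a linear ramp crosses 0.5 at its midpoint),
  # which leaves staircase terraces at coarse slice spacing. Shape-based
  # interpolation instead: per-slice signed distance transforms are
  # interpolated in z and thresholded at 0, so cross-sections morph
  # smoothly between slices. Identity resampling stays exact.
  ratio <- sp[3] / s_in
  if (ratio > 1.01) {
    sd <- vapply(seq_len(d[3]), function(k) signed_distance2d(node$mask[, , k]),
                 matrix(0, d[1], d[2]))
    # SDF extrapolation one slice beyond each end reconstructs the node
    # caps (the tissue between the outermost contoured slice and the true
    # node tip); quadratic extrapolation follows the ellipsoidal taper,
    # the linear fallback needs only two slices
    sdp <- array(0, d + c(0L, 0L, 2L))
    sdp[, , 1 + seq_len(d[3])] <- sd
    if (d[3] >= 3) {
      sdp[, , 1] <- 3 * sd[, , 1] - 3 * sd[, , 2] + sd[, , 3]
      sdp[, , d[3] + 2] <- 3 * sd[, , d[3]] - 3 * sd[, , d[3] - 1] +
        sd[, , d[3] - 2]
    } else {
      sdp[, , 1] <- 2 * sd[, , 1] - sd[, , 2]
      sdp[, , d[3] + 2] <- 2 * sd[, , d[3]] - sd[, , d[3] - 1]
    }
    nz_out <- floor((d[3] + 1) * sp[3] / s_in) + 1
    outdim <- c(d[1], d[2], as.integer(nz_out))
    sdi <- resample_z_catmull(sdp, step[3], as.integer(nz_out))
    mask_iso <- sdi >= 0
    volp <- array(0, d + c(0L, 0L, 2L))
    volp[, , 1 + seq_len(d[3])] <- node$volume
    volp[, , 1] <- node$volume[, , 1]
    volp[, , d[3] + 2] <- node$volume[, , d[3]]
    vol_iso <- array(cpp_resample_trilinear(as.numeric(volp), dim(volp),
                                            outdim, step), outdim)
  } else {
    mi <- cpp_resample_trilinear(as.numeric(node$mask), d, outdim, step)
    mask_iso <- array(mi >= 0.5, outdim)
    vol_iso <- array(cpp_resample_trilinear(as.numeric(node$volume), d,
                                            outdim, step), outdim)
  }

  # pad so the isosurface closes at the array border, blur for sub-voxel
  # placement, then march
  pad <- 3L
  pd <- outdim + 2L * pad
  field <- array(0, pd)
  field[pad + seq_len(outdim[1]), pad + seq_len(outdim[2]),
        pad + seq_len(outdim[3])] <- as.numeric(mask_iso)
  field <- cpp_gauss_blur3(as.numeric(field), pd, c(1, 1, 1))
  mt <- cpp_march_tets(field, pd, 0.5)
  if (nrow(mt$vertices) < 4L)
    nr_stop("noderad_degenerate_3d", "surface extraction failed (node too small)")
  v <- laplacian_smooth(mt$vertices, mt$faces, lambda = 0.5, passes = 1)
  v <- (v - pad) * s_in  # voxel coords -> mm (isotropic)

  structure(list(mask = mask_iso, volume = vol_iso, spacing = s_in,
                 vertices = v, faces = mt$faces, node_id = node$node_id),
            class = "node_model3d")
}
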