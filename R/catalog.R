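# The immutable 460-feature catalog (6 types, 26 subsets) and the
# per-node extraction driver.

glcm_types <- function() c(
  "Cluster Shade", "Cluster Proximity", "Contrast", "Correlation",
  "Different Entropy", "Different Variance", "Dissimilarity", "Energy",
  "Entropy", "Homogeneity Normalized", "Homogeneity", "InfoCorrelation1",
  "InfoCorrelation2", "Max Probability", "Sum Average", "Sum Entropy",
  "Sum of variance", "Variance")

# internal name mapping: catalog subset label "Different Entropy" etc. is
# the Haralick statistic computed by glcm_features() under the same name
glcm_stat_key <- function(type) {
  switch(type, "Different Entropy" = "Different Entropy",
         "Different Variance" = "Different Variance", type)
}

glcm_configs <- function() {
  g <- expand.grid(angle = c(0, 45, 90, 135), distance = 1:5)
  g <- g[order(g$distance, g$angle), ]
  rownames(g) <- NULL
  g
}

glszm_names <- function() c(
  "Small area emphasis", "Large area emphasis", "Low intensity emphasis",
  "High intensity emphasis", "Low intensity small area emphasis",
  "Low intensity large area emphasis", "High intensity small area emphasis",
  "High intensity large area emphasis", "Intensity variance",
  "Size zone variance", "Zone%")

gray_level_names <- function() c(
  "Mean", "Median", "Variance", "Standard deviation", "Max Pixel Value",
  "Min Pixel Value", "Skewness", "Kurtosis", "Energy", "Entropy", "Range")

shape3d_names <- function() c(
  "Volume", "Surface", "Equivalent diameter", "Extent",
  "Principal Axis Length 1", "Principal Axis Length 2",
  "Principal Axis Length 3", "Orientation1", "Orientation2", "Orientation3",
  "Eccentricity", "Solidity", "Convex volume", "Convex surface", "Convexity",
  "Compactness", "Rectangularity", "Elongation", "Roundness",
  "Area volume ratio", "Aspect radius 1", "Aspect radius 2",
  "Aspect radius 3", "Max radius", "Bounding box volume", "Ellipticity",
  "Defect ratio", "Gaussian Curvature sum", "Mean Curvature sum")

shape2d_names <- function() c(
  "Area", "Perimeter", "Major Axis Length", "Minor Axis Length",
  "Orientation", "Convexity", "Convex Area", "Convex Perimeter",
  "Maximum radius", "Bounding Box Area", "Defects Ratio",
  "Perimeter Area Ratio", "Aspect Ratio", "Bending Energy", "Eccentricity",
  "Equivalent Diameter", "Solidity", "Extent", "Compactness",
  "Rectangularity", "Elongation", "Roundness", "Ellipticity", "Sphericity")

edge_names <- function() c(
  "Mean inside", "Mean outside", "SD inside", "SD outside",
  "Mean difference", "SD difference")

#' The fixed feature catalog: 6 types, 26 subsets, 460 features
#'
#' 18 co-occurrence statistics, each over 20 (distance 1..5 x angle
#' 0/45/90/135) configurations named `D<d>A<a>`; 11 size-zone features;
#' 11 gray-level statistics; 29 3D and 24 2D morphology features; 6
#' boundary features at each disc radius 3/5/10; 7 Hu invariant moments.
#' The catalog is a pure constant: identical across runs and platforms.
#'
#' @return an object of class `feature_catalog`: `types` (6 names),
#'   `subsets` (26 entries with `name`, `type`, `source`, `features`),
#'   and `total_count` (460).
#' @export
feature_catalog <- function() {
  cfg <- glcm_configs()
  cfg_tag <- sprintf("D%dA%d", cfg$distance, cfg$angle)
  subsets <- list()
  for (tp in glcm_types()) {
    subsets[[tp]] <- list(
      name = tp, type = "Gray-Level Co-occurrence Matrix",
      source = "inscribed-square",
      features = paste("GLCM", tp, cfg_tag))
  }
  subsets[["GLSZM"]] <- list(
    name = "GLSZM", type = "Gray-Level Size Zone Matrix",
    source = "inscribed-square",
    features = paste("GLSZM", glszm_names()))
  subsets[["Gray-Level"]] <- list(
    name = "Gray-Level", type = "Gray-Level", source = "largest-section",
    features = paste("Gray", gray_level_names()))
  subsets[["3D Morphology"]] <- list(
    name = "3D Morphology", type = "LN morphology", source = "3D-model",
    features = paste("3D", shape3d_names()))
  subsets[["2D Morphology"]] <- list(
    name = "2D Morphology", type = "LN morphology", source = "largest-section",
    features = paste("2D", shape2d_names()))
  for (r in c(3, 5, 10)) {
    nm <- paste("Edge", r)
    subsets[[nm]] <- list(
      name = nm, type = "LN boundary", source = "boundary-band",
      features = paste(nm, edge_names()))
  }
  subsets[["Invariant moment"]] <- list(
    name = "Invariant moment", type = "Invariant moment",
    source = "inscribed-square",
    features = paste("Hu moment", 1:7))

  feats <- unlist(lapply(subsets, `[[`, "features"), use.names = FALSE)
  stopifnot(length(feats) == 460L, !anyDuplicated(feats),
            length(subsets) == 26L)
  structure(list(
    types = c("Gray-Level Co-occurrence Matrix", "Gray-Level Size Zone Matrix",
              "Gray-Level", "LN morphology", "LN boundary", "Invariant moment"),
    subsets = subsets, feature_names = feats, total_count = length(feats)),
    class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d features in %d subsets / %d types\n",
              x$total_count, length(x$subsets), length(x$types)))
  invisible(x)
}

#' Feature names of one or more catalog subsets
#' @param subsets character vector of subset names (e.g. `"GLSZM"`,
#'   `"Edge 5"`, `"Sum of variance"`).
#' @param catalog a [feature_catalog()].
#' @return character vector of member feature names, catalog-ordered.
#' @export
subset_features <- function(subsets, catalog = feature_catalog()) {
  bad <- setdiff(subsets, names(catalog$subsets))
  if (length(bad))
    nr_stop("noderad_parameter_error", "unknown subset(s): %s",
            paste(bad, collapse = ", "))
  feats <- unlist(lapply(catalog$subsets[subsets], `[[`, "features"),
                  use.names = FALSE)
  catalog$feature_names[catalog$feature_names %in% feats]
}

#' Export the catalog as JSON
#' @param path output file.
#' @param catalog a [feature_catalog()].
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(path, catalog = feature_catalog()) {
  jsonlite::write_json(
    list(types = catalog$types,
         subsets = lapply(unname(catalog$subsets), function(s)
           list(name = s$name, type = s$type, source = s$source,
                features = s$features)),
         total_count = catalog$total_count),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Extract the full 460-feature vector for one node
#'
#' Runs every extractor on its designated source region: GLCM/GLSZM/Hu
#' on the inscribed square of the largest section, gray-level and 2D
#' morphology on the largest section, boundary features on the
#' inside/outside bands, 3D morphology on the isotropic surface model.
#' Nodes whose 3D model is degenerate (single slice) get imputed zeros
#' for the 3D subset with a warning, keeping vectors rectangular.
#'
#' @param node a [node_image()].
#' @param catalog a [feature_catalog()].
#' @param levels gray levels for texture quantization (16).
#' @return named numeric vector of length 460 in catalog order, with
#'   attributes `node_id` and `label`.
#' @export
extract_all <- function(node, catalog = feature_catalog(), levels = 16) {
  geom <- section_geometry(node)
  patch <- inscribed_patch(node, geom)
  q <- quantize_gray(patch, levels)

  vals <- numeric(0)
  cfg <- glcm_configs()
  glcm_mat <- vector("list", nrow(cfg))
  for (k in seq_len(nrow(cfg)))
    glcm_mat[[k]] <- glcm(q, cfg$angle[k], cfg$distance[k], levels)
  glcm_stats <- vapply(glcm_mat, glcm_features, numeric(18))
  for (tp in glcm_types()) {
    v <- glcm_stats[glcm_stat_key(tp), ]
    names(v) <- catalog$subsets[[tp]]$features
    vals <- c(vals, v)
  }

  v <- glszm_features(q)
  names(v) <- catalog$subsets[["GLSZM"]]$features
  vals <- c(vals, v)

  v <- gray_level_features(geom$section_image[geom$section_mask])
  names(v) <- catalog$subsets[["Gray-Level"]]$features
  vals <- c(vals, v)

  v3 <- tryCatch(shape3d(build_3d_node(node)),
                 noderad_degenerate_3d = function(e) {
                   nr_warn("node %s: %s -- imputing 0 for 3D features",
                           node$node_id, conditionMessage(e))
                   setNames(numeric(29), shape3d_names())
                 })
  names(v3) <- catalog$subsets[["3D Morphology"]]$features
  vals <- c(vals, v3)

  v <- shape2d(geom$section_mask, spacing = node$spacing[1])
  names(v) <- catalog$subsets[["2D Morphology"]]$features
  vals <- c(vals, v)

  for (r in c(3, 5, 10)) {
    nm <- paste("Edge", r)
    v <- edge_features(geom$section_image, geom$boundary_bands[[paste0("r", r)]])
    names(v) <- catalog$subsets[[nm]]$features
    vals <- c(vals, v)
  }

  v <- invariant_moments(patch)
  names(v) <- catalog$subsets[["Invariant moment"]]$features
  vals <- c(vals, v)

  stopifnot(identical(names(vals), catalog$feature_names))
  vals[!is.finite(vals)] <- 0
  attr(vals, "node_id") <- node$node_id
  attr(vals, "label") <- node$label %||% NA_character_
  vals
}

#' Assemble a feature table from a list of nodes
#' @param nodes list of [node_image()] objects.
#' @param catalog a [feature_catalog()].
#' @return data.frame with `node_id`, `label`, and 460 feature columns.
#' @export
extract_table <- function(nodes, catalog = feature_catalog()) {
  rows <- lapply(nodes, function(nd) extract_all(nd, catalog))
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  data.frame(node_id = vapply(rows, attr, "", "node_id"),
             label = vapply(rows, attr, "", "label"),
             tab, check.names = FALSE)
}

#' Write / read a feature table as CSV (lossless names)
#' @param table data.frame from [extract_table()].
#' @param path CSV file path.
#' @return `path` / the table.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, check.names = FALSE)
}

# split a feature table into (X matrix, y factor) for the classifiers
table_xy <- function(table, features = NULL) {
  meta <- intersect(c("node_id", "label", "split"), names(table))
  feats <- features %||% setdiff(names(table), meta)
  missing <- setdiff(feats, names(table))
  if (length(missing))
    nr_stop("noderad_schema_error", "missing feature column(s): %s",
            paste(head(missing, 5), collapse = ", "))
  X <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  y <- if ("label" %in% names(table))
    factor(table$label, levels = node_classes()) else NULL
  list(X = X, y = y, features = feats)
}
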