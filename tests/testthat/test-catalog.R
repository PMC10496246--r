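# feature_catalog: the fixed 460-feature schema and the extraction driver

test_that("the catalog is the fixed 6-type / 26-subset / 460-feature schema", {
  cat460 <- feature_catalog()
  expect_equal(cat460$total_count, 460)
  expect_length(cat460$subsets, 26)
  expect_length(cat460$types, 6)
  expect_false(anyDuplicated(cat460$feature_names) > 0)

  sizes <- vapply(cat460$subsets, function(s) length(s$features), 0)
  glcm_subsets <- names(sizes)[vapply(cat460$subsets, function(s)
    s$type == "Gray-Level Co-occurrence Matrix", TRUE)]
  expect_length(glcm_subsets, 18)
  expect_true(all(sizes[glcm_subsets] == 20))
  expect_equal(unname(sizes[["GLSZM"]]), 11)
  expect_equal(unname(sizes[["Gray-Level"]]), 11)
  expect_equal(unname(sizes[["3D Morphology"]]), 29)
  expect_equal(unname(sizes[["2D Morphology"]]), 24)
  expect_true(all(sizes[c("Edge 3", "Edge 5", "Edge 10")] == 6))
  expect_equal(unname(sizes[["Invariant moment"]]), 7)
  expect_equal(sum(sizes), 460)

  # pure constant
  expect_identical(feature_catalog(), cat460)
})

test_that("the seven coarse-pool subsets union to 89 features", {
  pool <- subset_features(c("Sum of variance", "GLSZM", "Gray-Level",
                            "3D Morphology", "Edge 3", "Edge 5", "Edge 10"))
  expect_length(pool, 89)
  expect_error(subset_features("No Such Subset"),
               class = "noderad_parameter_error")
})

test_that("extract_all returns a complete, deterministic, catalog-ordered vector", {
  nd <- generate_node(phantom_spec(), "metastatic", seed = 9)
  fv <- extract_all(nd)
  expect_length(fv, 460)
  expect_identical(names(fv), feature_catalog()$feature_names)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all(nd))
  expect_equal(attr(fv, "label"), "metastatic")
})

test_that("degenerate 3D nodes impute zeros with a warning", {
  mask <- array(FALSE, c(40, 40, 1)); mask[10:30, 10:30, 1] <- TRUE
  nd <- node_image(array(120, c(40, 40, 1)), mask, c(1, 1, 3))
  expect_warning(fv <- extract_all(nd), "imputing 0")
  feats3d <- subset_features("3D Morphology")
  expect_true(all(fv[feats3d] == 0))
  expect_length(fv, 460)
})

test_that("feature tables round-trip losslessly through CSV", {
  nodes <- lapply(1:2, function(s)
    generate_node(phantom_spec(), "normal", seed = s))
  tab <- extract_table(nodes)
  expect_equal(dim(tab), c(2, 462))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  tab2 <- read_feature_table(path)
  expect_identical(names(tab2), names(tab))
  expect_equal(as.matrix(tab2[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12)
})

test_that("the catalog JSON export carries the whole schema", {
  path <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$total_count, 460)
  expect_equal(length(obj$subsets$name), 26)
})
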