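# synthetic_data: phantom determinism, cohort bookkeeping, planted tables

test_that("phantoms are bit-identical for identical (spec, class, seed)", {
  spec <- phantom_spec()
  a <- generate_node(spec, "ENE", seed = 123)
  b <- generate_node(spec, "ENE", seed = 123)
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)
  c <- generate_node(spec, "ENE", seed = 124)
  expect_false(identical(a$volume, c$volume))
})

test_that("zero surface perturbation gives near-unit solidity", {
  spec <- phantom_spec(surface_amp = c(normal = 0, metastatic = 0, ENE = 0))
  nd <- generate_node(spec, "normal", seed = 5)
  f <- shape3d(build_3d_node(nd))
  expect_gt(f[["Solidity"]], 0.98)
})

test_that("impossible geometry is rejected", {
  spec <- phantom_spec(axes_mm = c(0.2, 0.3))
  expect_error(generate_node(spec, "normal", seed = 1),
               class = "noderad_spec_error")
})

test_that("cohorts split 8:2 stratified with a faithful manifest", {
  spec <- phantom_spec(counts = c(normal = 10, metastatic = 10, ENE = 10),
                       seed = 2)
  coh <- generate_cohort(spec)
  m <- coh$manifest
  expect_equal(nrow(m), 30)
  expect_equal(sum(m$split == "train"), 24)
  expect_equal(sum(m$split == "test"), 6)
  for (cl in node_classes()) {
    expect_equal(sum(m$label == cl & m$split == "train"), 8)
    expect_equal(sum(m$label == cl & m$split == "test"), 2)
  }
  expect_identical(m$node_id, vapply(coh$nodes, `[[`, "", "node_id"))
  expect_identical(m$label,
                   vapply(coh$nodes, function(n) n$label, ""))

  # regeneration from manifest seeds reproduces identical volumes
  i <- 7
  nd <- generate_node(spec, m$label[i], m$seed[i])
  expect_identical(nd$volume, coh$nodes[[i]]$volume)
})

test_that("cohort bundles round-trip through a directory", {
  spec <- phantom_spec(counts = c(normal = 2, metastatic = 2, ENE = 2),
                       seed = 3)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  nd <- read_node_bundle(dir, coh$manifest$node_id[1])
  expect_identical(nd$volume, coh$nodes[[1]]$volume)
})

test_that("planted tables carry the promised signal structure", {
  spec0 <- table_spec(n_per_class = 40, p = 12, k = 0, effect = 0, seed = 4)
  tab0 <- generate_table(spec0)
  y <- factor(tab0$label, levels = node_classes())
  acc0 <- svm_cv_accuracy(as.matrix(tab0[, -(1:2)]), y,
                          make_folds(y, 5, 1), C = 1, gamma = 0.1)
  expect_lt(abs(acc0 - 1 / 3), 0.12)  # null case: chance

  spec5 <- table_spec(n_per_class = 40, p = 12, k = 3, effect = 5, seed = 4)
  tab5 <- generate_table(spec5)
  expect_identical(attr(tab5, "informative"), c("F001", "F002", "F003"))
  # near-linear kernel on the informative columns: large-margin regime
  acc5 <- svm_cv_accuracy(as.matrix(tab5[, attr(tab5, "informative")]),
                          y, make_folds(y, 5, 1), C = 16, gamma = 0.01)
  expect_gte(acc5, 0.99)

  expect_identical(generate_table(spec5), generate_table(spec5))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_node(phantom_spec(), "normal", seed = 17))
  invisible(generate_table(table_spec(seed = 17)))
  expect_identical(.Random.seed, before)
})
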