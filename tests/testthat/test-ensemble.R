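# ensemble_classifier: member training, voting, tie-breaks, binary views

small_cfg <- function(seed = 1)
  ibcga_config(n_pop = 6, g_max = 2, r_start = 6, r_end = 3,
               cv_folds = 5, seed = seed)

# a hand-built ensemble whose members vote deterministically via
# "trivial" pairwise models (no support vectors, fixed decision sign)
fixed_member <- function(vote, levels = node_classes()) {
  k <- length(levels)
  pairs <- list()
  combs <- utils::combn(k, 2)
  for (p in seq_len(ncol(combs))) {
    a <- combs[1, p]; b <- combs[2, p]
    sign <- if (match(vote, levels) == a) 1 else if (match(vote, levels) == b)
      -1 else 0
    pairs[[p]] <- list(classes = c(a, b), trivial = TRUE,
                       trivial_sign = sign,  # 0 for the irrelevant pair
                       b = 0, sv = matrix(0, 0, 1), coef = numeric(0))
  }
  svm <- structure(list(levels = levels, C = 1, gamma = 1,
                        center = c(F001 = 0), scale = c(F001 = 1),
                        features = "F001", pairs = pairs),
                   class = "noderad_svm")
  list(svm = svm, features = "F001", C = 1, gamma = 1, fitness = 1, m = 1,
       med = data.frame(feature = "F001", med = 0), seed = 0)
}

fixed_ensemble <- function(votes) {
  structure(list(members = lapply(votes, fixed_member),
                 levels = node_classes(),
                 selection_freq = data.frame(feature = "F001",
                                             times_selected = length(votes)),
                 pool = "F001", config = NULL, n_members = length(votes)),
            class = "noderad_ensemble")
}

one_row <- data.frame(node_id = "n1", F001 = 0)

test_that("plurality voting and the vote-fraction scores", {
  ens <- fixed_ensemble(rep(node_classes(), c(5, 6, 20)))
  pred <- predict_ensemble(ens, one_row)
  expect_equal(as.character(pred$predicted), "ENE")
  expect_false(pred$tie)
  expect_equal(pred$ene_score, 20 / 31)
  expect_equal(pred$met_score, 26 / 31)
  expect_equal(pred$normal + pred$metastatic + pred$ENE, 31)
})

test_that("unanimous members give degenerate scores", {
  ens <- fixed_ensemble(rep("normal", 31))
  pred <- predict_ensemble(ens, one_row)
  expect_equal(as.character(pred$predicted), "normal")
  expect_equal(pred$ene_score, 0)
  expect_equal(pred$met_score, 0)
})

test_that("ties fall through confidence to the severity order", {
  # 13/13/5: normal and metastatic tie on votes and on (symmetric)
  # trivial confidences; severity prefers metastatic
  ens <- fixed_ensemble(rep(node_classes(), c(13, 13, 5)))
  pred <- predict_ensemble(ens, one_row)
  expect_true(pred$tie)
  expect_equal(as.character(pred$predicted), "metastatic")
})

test_that("missing feature columns raise a schema error naming them", {
  ens <- fixed_ensemble(rep("normal", 3))
  expect_error(predict_ensemble(ens, data.frame(node_id = "n1", other = 1)),
               regexp = "F001", class = "noderad_schema_error")
})

test_that("binary views map three-class calls onto the two tasks", {
  pred <- data.frame(predicted = factor(c("metastatic", "ENE", "normal"),
                                        levels = node_classes()),
                     ene_score = c(0.2, 0.8, 0.0),
                     met_score = c(0.9, 1.0, 0.1))
  truth <- c("ENE", "ENE", "normal")
  bv <- binary_views(pred, truth)
  # node 1: predicted metastatic, truth ENE
  expect_false(bv$ene$pred[1]); expect_true(bv$ene$truth[1])   # ENE-task FN
  expect_true(bv$metastasis$pred[1]); expect_true(bv$metastasis$truth[1])  # met-task TP
  # all-correct three-class predictions imply perfect binary accuracy
  bv2 <- binary_views(pred, c("metastatic", "ENE", "normal"))
  expect_equal(mean(bv2$ene$pred == bv2$ene$truth), 1)
  expect_equal(mean(bv2$metastasis$pred == bv2$metastasis$truth), 1)
})

test_that("random votes give near-chance AUC under the permutation null", {
  set.seed(33)
  n <- 400
  score <- runif(n)
  truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
  expect_lt(abs(roc_auc(score, truth)$auc - 50), 8)
})

test_that("trained ensembles have the configured member count and determinism", {
  tab <- generate_table(table_spec(15, 10, 3, 3, 7))
  ens <- train_ensemble(tab, config = small_cfg(3), n_members = 5)
  expect_length(ens$members, 5)
  expect_true(all(vapply(ens$members, function(m)
    all(m$features %in% ens$pool), TRUE)))
  ens2 <- train_ensemble(tab, config = small_cfg(3), n_members = 5)
  expect_identical(predict_ensemble(ens, tab), predict_ensemble(ens2, tab))

  # planted features dominate the selection-frequency report
  freq <- ens$selection_freq
  informative_hits <- sum(freq$times_selected[freq$feature %in%
                                                attr(tab, "informative")])
  noise_hits <- sum(freq$times_selected) - informative_hits
  expect_gt(informative_hits / 3, noise_hits / 7)  # per-feature average
})

test_that("prediction is invariant to row and feature-column order", {
  tab <- generate_table(table_spec(15, 10, 3, 3, 8))
  ens <- train_ensemble(tab, config = small_cfg(4), n_members = 3)
  pred <- predict_ensemble(ens, tab)
  perm_cols <- tab[, c(1, 2, sample(3:12))]
  pred2 <- predict_ensemble(ens, perm_cols)
  expect_identical(pred$predicted, pred2$predicted)
  shuffle <- sample(nrow(tab))
  pred3 <- predict_ensemble(ens, tab[shuffle, ])
  expect_identical(as.character(pred3$predicted),
                   as.character(pred$predicted[shuffle]))
})

test_that("ensembles survive the JSON round trip", {
  tab <- generate_table(table_spec(12, 8, 2, 3, 9))
  ens <- train_ensemble(tab, config = small_cfg(5), n_members = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_ensemble(ens, path)
  ens2 <- load_ensemble(path)
  p1 <- predict_ensemble(ens, tab)
  p2 <- predict_ensemble(ens2, tab)
  expect_equal(as.character(p1$predicted), as.character(p2$predicted))
  expect_equal(p1$ene_score, p2$ene_score, tolerance = 1e-12)
})
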