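# Coarse feature selection: rank the 26 catalog subsets by
# cross-validated SVM accuracy on three prediction tasks and pool the
# top five per task.

#' The three coarse-evaluation tasks
#'
#' (1) normal vs metastatic, where the metastatic side includes ENE
#' nodes (pathologically ENE is a subset of metastatic disease);
#' (2) ENE vs non-ENE; (3) the full three-class problem.
#'
#' @return named list of label-mapping functions (factor -> factor).
#' @export
coarse_tasks <- function() {
  list(
    "met-vs-normal" = function(y)
      factor(ifelse(y == "normal", "normal", "metastatic"),
             levels = c("normal", "metastatic")),
    "ene-vs-rest" = function(y)
      factor(ifelse(y == "ENE", "ENE", "non-ENE"),
             levels = c("non-ENE", "ENE")),
    "three-class" = function(y) factor(y, levels = node_classes()))
}

#' Rank feature subsets by cross-validated SVM accuracy
#'
#' For each of the 26 catalog subsets and each of the three tasks, fits
#' an RBF SVM on that subset's features alone (best of a small 3x3
#' C/gamma grid, since the coarse stage states no hyperparameters) and
#' records stratified k-fold CV accuracy. The candidate pool is the
#' union of the top five subsets per task. Deterministic given `seed`.
#'
#' @param table feature table with `label` column.
#' @param folds CV folds (10).
#' @param seed fold-assignment seed.
#' @param catalog a [feature_catalog()].
#' @param grid_C,grid_gamma coarse hyperparameter grid.
#' @return an object of class `subset_ranking`: `rankings` (one ordered
#'   data.frame per task), `pool_subsets`, `pool_features`, `seed`.
#' @export
evaluate_subsets <- function(table, folds = 10, seed = 1,
                             catalog = feature_catalog(),
                             grid_C = 2^c(0, 4, 8),
                             grid_gamma = 2^c(-7, -4, -1)) {
  xy <- table_xy(table)
  if (is.null(xy$y)) nr_stop("noderad_input_error", "table must carry labels")
  if (nlevels(droplevels(xy$y)) < 2)
    nr_stop("noderad_input_error", "need >= 2 classes")
  tasks <- coarse_tasks()
  subset_names <- names(catalog$subsets)

  rankings <- lapply(names(tasks), function(tn) {
    y_task <- tasks[[tn]](xy$y)
    fold <- make_folds(y_task, folds, seed)
    acc <- vapply(subset_names, function(sn) {
      feats <- subset_features(sn, catalog)
      X <- xy$X[, feats, drop = FALSE]
      max(vapply(grid_C, function(C)
        vapply(grid_gamma, function(g)
          svm_cv_accuracy(X, y_task, fold, C, g), 0), numeric(length(grid_gamma))))
    }, 0)
    o <- order(-acc, subset_names)  # deterministic tie-break by name
    data.frame(subset = subset_names[o], accuracy = unname(acc[o]))
  })
  names(rankings) <- names(tasks)

  top5 <- lapply(rankings, function(r) r$subset[1:5])
  pool_subsets <- subset_names[subset_names %in% unique(unlist(top5))]
  structure(list(rankings = rankings, top5 = top5,
                 pool_subsets = pool_subsets,
                 pool_features = subset_features(pool_subsets, catalog),
                 folds = folds, seed = seed),
            class = "subset_ranking")
}

#' @export
print.subset_ranking <- function(x, ...) {
  cat("<subset_ranking>\n")
  for (tn in names(x$rankings)) {
    r <- x$rankings[[tn]]
    cat(sprintf("  %s: %s\n", tn,
                paste(sprintf("%s (%.3f)", r$subset[1:5], r$accuracy[1:5]),
                      collapse = ", ")))
  }
  cat(sprintf("  pool: %d subsets, %d features\n",
              length(x$pool_subsets), length(x$pool_features)))
  invisible(x)
}

#' Write / read a subset ranking as JSON
#' @param ranking a `subset_ranking`. @param path file path.
#' @return `path` / the ranking.
#' @export
write_ranking_json <- function(ranking, path) {
  jsonlite::write_json(
    list(rankings = ranking$rankings, top5 = ranking$top5,
         pool_subsets = ranking$pool_subsets,
         pool_features = ranking$pool_features,
         folds = ranking$folds, seed = ranking$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ranking_json
#' @export
read_ranking_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "subset_ranking")
}
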