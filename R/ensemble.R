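# Voting ensemble of independently selected SVM models. Each member is
# one seeded IBCGA run retrained on the full training table with its
# selected features and (C, gamma); prediction is by plurality over the
# members' three-class votes, with a documented tie-break chain
# (summed decision confidence, then severity ENE > metastatic > normal).

#' Train the SVM voting ensemble
#'
#' Runs the IBCGA `n_members` times with seeds `seed + 0 ..
#' seed + n_members - 1` on the candidate pool, retrains each selected
#' model on the full training table, and reports the per-feature
#' selection frequency across members (the interpretability readout).
#'
#' @param table training feature table with `label`.
#' @param pool candidate-pool feature names (e.g. from
#'   [evaluate_subsets()]); default all feature columns.
#' @param config an [ibcga_config()]; its `seed` is the master seed.
#' @param n_members ensemble size (31).
#' @return an object of class `noderad_ensemble`: `members` (each with
#'   `svm`, `features`, `C`, `gamma`, `fitness`, `med`), `selection_freq`
#'   (data.frame), `pool`, `config`.
#' @export
train_ensemble <- function(table, pool = NULL, config = ibcga_config(),
                           n_members = 31) {
  xy <- table_xy(table, pool)
  y <- droplevels(xy$y)
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + (i - 1L)
    fit <- ibcga_run(xy$X, features = xy$features, config = cfg_i, y = y)
    svm <- svm_train(xy$X[, fit$features, drop = FALSE], y,
                     C = fit$C, gamma = fit$gamma, features = fit$features)
    members[[i]] <- list(svm = svm, features = fit$features, C = fit$C,
                         gamma = fit$gamma, fitness = fit$fitness,
                         m = fit$m, med = fit$med, seed = cfg_i$seed)
  }
  freq <- sort(table(unlist(lapply(members, `[[`, "features"))),
               decreasing = TRUE)
  structure(list(
    members = members, levels = levels(y),
    selection_freq = data.frame(feature = names(freq),
                                times_selected = as.integer(freq)),
    pool = xy$features, config = config, n_members = n_members),
    class = "noderad_ensemble")
}

#' @export
print.noderad_ensemble <- function(x, ...) {
  cat(sprintf("<noderad_ensemble> %d members over a %d-feature pool\n",
              length(x$members), length(x$pool)))
  cat("most-selected features:\n")
  print(head(x$selection_freq, 8), row.names = FALSE)
  invisible(x)
}

#' Predict node classes by majority vote
#'
#' Each member votes one of normal/metastatic/ENE; the final class is
#' the plurality. Ties are broken by the higher summed SVM decision
#' confidence among the tied classes, then by severity
#' (ENE > metastatic > normal); tied nodes carry `tie = TRUE`. The ENE
#' score is the ENE vote fraction and the metastasis score the
#' metastatic-or-ENE vote fraction.
#'
#' @param model a `noderad_ensemble`.
#' @param table feature table containing every feature any member uses.
#' @return data.frame: `node_id`, per-class vote counts, `predicted`,
#'   `tie`, `ene_score`, `met_score`.
#' @export
predict_ensemble <- function(model, table) {
  xy <- table_xy(table, features = NULL)
  need <- unique(unlist(lapply(model$members, `[[`, "features")))
  missing <- setdiff(need, colnames(xy$X))
  if (length(missing))
    nr_stop("noderad_schema_error", "missing feature column(s): %s",
            paste(missing, collapse = ", "))
  n <- nrow(xy$X)
  k <- length(model$levels)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model$levels))
  conf <- matrix(0, n, k, dimnames = list(NULL, model$levels))
  for (mb in model$members) {
    pr <- svm_predict(mb$svm, xy$X[, mb$features, drop = FALSE])
    idx <- cbind(seq_len(n), as.integer(pr$class))
    votes[idx] <- votes[idx] + 1L
    conf <- conf + pr$decision
  }
  severity <- match(model$levels, node_classes())  # higher = more severe
  predicted <- character(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1) {
      tie[i] <- TRUE
      cbest <- top[conf[i, top] == max(conf[i, top])]
      top <- cbest[which.max(severity[cbest])]
    }
    predicted[i] <- model$levels[top[1]]
  }
  ene_votes <- if ("ENE" %in% colnames(votes)) votes[, "ENE"] else 0L
  met_votes <- ene_votes +
    (if ("metastatic" %in% colnames(votes)) votes[, "metastatic"] else 0L)
  data.frame(node_id = if ("node_id" %in% names(table)) table$node_id
             else sprintf("row%04d", seq_len(n)),
             votes, check.names = FALSE,
             predicted = factor(predicted, levels = model$levels),
             tie = tie,
             ene_score = ene_votes / length(model$members),
             met_score = met_votes / length(model$members))
}

#' Binary task views of three-class predictions
#'
#' ENE task: positive iff the final class is ENE (truth positive iff
#' ENE). Metastasis task: positive iff the final class is metastatic or
#' ENE (truth likewise). Vote-fraction scores are attached for ROC.
#'
#' @param pred data.frame from [predict_ensemble()].
#' @param truth factor/character of true labels, aligned with `pred`.
#' @return list of two data.frames `ene` and `metastasis`, each with
#'   `pred`, `truth` (logicals) and `score`.
#' @export
binary_views <- function(pred, truth) {
  if (length(truth) != nrow(pred))
    nr_stop("noderad_input_error", "truth length mismatch")
  truth <- as.character(truth)
  list(
    ene = data.frame(
      pred = pred$predicted == "ENE",
      truth = truth == "ENE",
      score = pred$ene_score),
    metastasis = data.frame(
      pred = pred$predicted %in% c("metastatic", "ENE"),
      truth = truth %in% c("metastatic", "ENE"),
      score = pred$met_score))
}

# ---------------------------------------------------------------------------
# persistence (single JSON file, versioned)

#' Save / load an ensemble as JSON
#' @param model a `noderad_ensemble`. @param path file path.
#' @return `path` / the restored ensemble.
#' @export
save_ensemble <- function(model, path) {
  ser_member <- function(mb) list(
    features = mb$features, C = mb$C, gamma = mb$gamma,
    fitness = mb$fitness, m = mb$m, seed = mb$seed,
    med = mb$med,
    svm = list(levels = mb$svm$levels, C = mb$svm$C, gamma = mb$svm$gamma,
               center = as.list(mb$svm$center), scale = as.list(mb$svm$scale),
               features = mb$svm$features,
               pairs = lapply(mb$svm$pairs, function(pm) list(
                 classes = pm$classes, trivial = pm$trivial,
                 trivial_sign = pm$trivial_sign, b = pm$b,
                 sv = as.list(as.data.frame(pm$sv)), coef = pm$coef))))
  jsonlite::write_json(
    list(schema = "noderad_ensemble_v1", levels = model$levels,
         n_members = model$n_members, pool = model$pool,
         selection_freq = model$selection_freq,
         members = lapply(model$members, ser_member)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "noderad_ensemble_v1"))
    nr_stop("noderad_schema_error", "unknown model schema")
  chr <- function(x) vapply(x, as.character, "")
  num <- function(x) vapply(x, as.numeric, 0)
  members <- lapply(obj$members, function(raw) {
    svm <- raw$svm
    feats <- chr(svm$features)
    pairs <- lapply(svm$pairs, function(pm) {
      sv_df <- pm$sv
      sv <- if (length(sv_df) == 0) {
        matrix(0, 0, length(feats))
      } else do.call(cbind, lapply(sv_df, num))
      colnames(sv) <- names(sv_df)
      list(classes = as.integer(num(pm$classes)),
           trivial = isTRUE(pm$trivial),
           trivial_sign = as.numeric(pm$trivial_sign), b = as.numeric(pm$b),
           sv = sv[, feats, drop = FALSE], coef = num(pm$coef))
    })
    mdl <- structure(list(
      levels = chr(svm$levels), C = as.numeric(svm$C),
      gamma = as.numeric(svm$gamma),
      center = setNames(num(svm$center), names(svm$center))[feats],
      scale = setNames(num(svm$scale), names(svm$scale))[feats],
      features = feats, pairs = pairs), class = "noderad_svm")
    list(svm = mdl, features = chr(raw$features), C = as.numeric(raw$C),
         gamma = as.numeric(raw$gamma), fitness = as.numeric(raw$fitness),
         m = as.integer(num(raw$m)),
         med = data.frame(feature = chr(lapply(raw$med, `[[`, "feature")),
                          med = num(lapply(raw$med, `[[`, "med"))),
         seed = as.numeric(raw$seed))
  })
  structure(list(
    members = members, levels = chr(obj$levels),
    selection_freq = data.frame(
      feature = chr(lapply(obj$selection_freq, `[[`, "feature")),
      times_selected = as.integer(num(lapply(obj$selection_freq,
                                             `[[`, "times_selected")))),
    pool = chr(obj$pool), config = NULL,
    n_members = as.integer(num(obj$n_members))),
    class = "noderad_ensemble")
}
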