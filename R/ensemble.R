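# Six-algorithm soft-voting ensemble: SVM, random forest, neural network,
# gradient-boosted trees, decision tree and k-nearest neighbors, each
# emitting class probabilities over (IA, IE, IS); the ensemble probability
# is their unweighted mean and the call is the argmax.

TME_CLASSES <- c("IA", "IE", "IS")

default_hyperparams <- function() {
  list(svm_kernel = "radial", rf_trees = 500, nnet_size = 16,
       nnet_maxit = 500, xgb_rounds = 300, xgb_depth = 3, tree_depth = 6,
       knn_k = 11)
}

#' Stratified train/validation split
#'
#' Draws `train_fraction` of each class into the training set so that class
#' proportions in the two splits match the cohort within one sample per
#' class. Deterministic given the seed.
#'
#' @param labels named class-label vector.
#' @param train_fraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return List with integer `train_idx` and `valid_idx` (disjoint,
#'   exhaustive).
#' @export
split_stratified <- function(labels, train_fraction = 0.75, seed = 1) {
  sizes <- table(labels)
  if (any(sizes < 4L)) {
    stop_("class(es) with fewer than 4 samples: %s",
          paste(names(sizes)[sizes < 4L], collapse = ", "))
  }
  train_idx <- integer(0)
  with_seed_(seed, {
    for (g in names(sizes)) {
      idx <- which(labels == g)
      n_tr <- round(length(idx) * train_fraction)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- unname(sort(train_idx))
  list(train_idx = train_idx,
       valid_idx = setdiff(seq_along(labels), train_idx))
}

# --- individual learners ----------------------------------------------------
# Each fitter returns an opaque model; each predictor returns an
# n x 3 probability matrix with columns in class order.

fit_learner <- function(name, x, y, hp, seed) {
  with_seed_(seed, switch(
    name,
    svm = e1071::svm(x, y, probability = TRUE, kernel = hp$svm_kernel),
    rf = randomForest::randomForest(x, y, ntree = hp$rf_trees),
    nnet = nnet::nnet(x, nnet::class.ind(y), size = hp$nnet_size,
                      softmax = TRUE, maxit = hp$nnet_maxit,
                      MaxNWts = 1e5, trace = FALSE),
    xgboost = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = nlevels(y),
                    max_depth = hp$xgb_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
      nrounds = hp$xgb_rounds, verbose = 0),
    dectree = rpart::rpart(
      .class ~ ., data = data.frame(.class = y, x, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(maxdepth = hp$tree_depth)),
    knn = caret::knn3(x, y, k = hp$knn_k),
    stop_("unknown learner '%s'", name)))
}

predict_learner <- function(name, model, x, classes) {
  p <- switch(
    name,
    svm = {
      pr <- stats::predict(model, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = stats::predict(model, x, type = "prob"),
    nnet = {
      pr <- stats::predict(model, x)
      if (is.null(colnames(pr))) colnames(pr) <- classes
      pr
    },
    xgboost = {
      pr <- stats::predict(model, xgboost::xgb.DMatrix(x))
      matrix(pr, ncol = length(classes), byrow = TRUE,
             dimnames = list(rownames(x), classes))
    },
    dectree = stats::predict(model, data.frame(x, check.names = FALSE),
                             type = "prob"),
    knn = stats::predict(model, x, type = "prob"),
    stop_("unknown learner '%s'", name))
  p <- p[, classes, drop = FALSE]
  rownames(p) <- rownames(x)
  # guard against tiny negative rounding and renormalize exactly
  p[p < 0] <- 0
  sweep(p, 1, rowSums(p), "/")
}

#' Train the six-model ensemble classifier
#'
#' Features are the panel genes z-scored with training-split statistics. The
#' cohort is split 3:1 (stratified) into training and validation sets, each
#' of the six learners is fitted on the training split, and classification
#' reports are computed on both splits.
#'
#' @param expr_log2 an [expression_matrix()] on log2 scale containing every
#'   panel gene.
#' @param labels named IE/IS/IA label vector over the cohort samples.
#' @param panel a [subtype_panel()].
#' @param seed base seed; per-learner sub-seeds are derived from it.
#' @param train_fraction stratified training fraction.
#' @param hyperparams list overriding [default hyperparameters][train_ensemble]
#'   (svm_kernel, rf_trees, nnet_size, nnet_maxit, xgb_rounds, xgb_depth,
#'   tree_depth, knn_k).
#' @return List with `model` (a `tme_ensemble`), `report_train` and
#'   `report_valid` ([classification_report()]s), and the split indices.
#' @export
train_ensemble <- function(expr_log2, labels, panel, seed = 1,
                           train_fraction = 0.75, hyperparams = list()) {
  if (expr_scale(expr_log2) != "log2") {
    stop_("train_ensemble expects log2-scale expression")
  }
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  genes <- panel_genes(panel)
  m <- unclass(expr_log2)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop_("panel gene(s) absent from training expression: %s",
          paste(missing, collapse = ", "))
  }
  labels <- labels[colnames(m)]
  if (length(unique(labels)) < 3L) {
    stop_("training requires all three subtypes to be represented")
  }
  split <- split_stratified(labels, train_fraction = train_fraction,
                            seed = seed)
  x_all <- t(m[genes, , drop = FALSE])
  colnames(x_all) <- make.names(genes, unique = TRUE)
  x_tr <- x_all[split$train_idx, , drop = FALSE]

  mu <- colMeans(x_tr)
  sdv <- apply(x_tr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  zscore <- function(x) sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z_tr <- zscore(x_tr)
  y_tr <- factor(labels[split$train_idx], levels = TME_CLASSES)

  learner_names <- c("svm", "rf", "nnet", "xgboost", "dectree", "knn")
  learners <- stats::setNames(lapply(seq_along(learner_names), function(i) {
    fit_learner(learner_names[i], z_tr, y_tr, hp, seed + 100L + i)
  }), learner_names)

  model <- structure(list(panel = panel, gene_order = genes,
                          feature_names = colnames(x_all),
                          feature_stats = list(mean = mu, sd = sdv),
                          learners = learners, class_order = TME_CLASSES,
                          hyperparams = hp, training_seed = seed,
                          version = as.character(utils::packageVersion("tmesubtyper"))),
                     class = "tme_ensemble")

  calls_tr <- ensemble_predict(model, zscore(x_tr))
  z_va <- zscore(x_all[split$valid_idx, , drop = FALSE])
  calls_va <- ensemble_predict(model, z_va)
  list(model = model,
       report_train = classification_report(labels[split$train_idx],
                                            calls_tr$label),
       report_valid = classification_report(labels[split$valid_idx],
                                            calls_va$label),
       split = split)
}

#' @export
print.tme_ensemble <- function(x, ...) {
  cat(sprintf("tme_ensemble: 6 learners (%s) on %d panel genes; classes %s\n",
              paste(names(x$learners), collapse = ", "),
              length(x$gene_order), paste(x$class_order, collapse = "/")))
  invisible(x)
}

#' Per-learner class probabilities
#'
#' @param model a `tme_ensemble`.
#' @param feature_matrix samples x features matrix aligned to
#'   `model$gene_order` and already z-scored.
#' @return Named list of six n x 3 probability matrices.
#' @export
predict_learner_probs <- function(model, feature_matrix) {
  x <- prepare_predict_matrix(model, feature_matrix)
  stats::setNames(lapply(names(model$learners), function(nm) {
    predict_learner(nm, model$learners[[nm]], x, model$class_order)
  }), names(model$learners))
}

prepare_predict_matrix <- function(model, feature_matrix) {
  x <- as.matrix(feature_matrix)
  if (ncol(x) != length(model$gene_order)) {
    stop_("feature matrix has %d columns; model expects %d",
          ncol(x), length(model$gene_order))
  }
  bad <- !apply(x, 1, function(r) all(is.finite(r)))
  if (any(bad)) {
    stop_("non-finite features for sample(s): %s",
          paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
  }
  colnames(x) <- model$feature_names
  x
}

#' Ensemble subtype prediction
#'
#' Averages the six learners' class-probability vectors with equal weights
#' and assigns each sample to the class with the highest ensemble
#' probability; exact ties break by class order (IA, then IE, then IS).
#'
#' @param model a `tme_ensemble`.
#' @param feature_matrix samples x features matrix aligned to
#'   `model$gene_order`, z-scored consistently with training (see
#'   [prepare_features()] for new cohorts).
#' @return A `subtype_calls` data.frame: `sample`, `P_IA`, `P_IE`, `P_IS`,
#'   `label`.
#' @export
ensemble_predict <- function(model, feature_matrix) {
  probs <- predict_learner_probs(model, feature_matrix)
  ens <- Reduce(`+`, probs) / length(probs)
  labels <- model$class_order[apply(ens, 1, which.max)]
  out <- data.frame(sample = rownames(ens),
                    P_IA = ens[, "IA"], P_IE = ens[, "IE"], P_IS = ens[, "IS"],
                    label = labels, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("subtype_calls", "data.frame")
  attr(out, "learner_probs") <- probs
  out
}
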