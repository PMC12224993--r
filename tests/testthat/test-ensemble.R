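test_that("stratified split keeps 3:1 class balance and is deterministic", {
  labels <- setNames(rep(c("IA", "IE", "IS"), each = 100),
                     sprintf("S%03d", 1:300))
  sp <- split_stratified(labels, seed = 4)
  expect_identical(sort(c(sp$train_idx, sp$valid_idx)), 1:300)
  expect_identical(as.integer(table(labels[sp$train_idx])), rep(75L, 3))
  expect_identical(as.integer(table(labels[sp$valid_idx])), rep(25L, 3))
  # proportions within one sample per class for unbalanced cohorts
  lab2 <- setNames(rep(c("IA", "IE", "IS"), times = c(41, 53, 67)),
                   sprintf("T%03d", 1:161))
  sp2 <- split_stratified(lab2, seed = 4)
  tr <- table(lab2[sp2$train_idx])
  expect_true(all(abs(tr - 0.75 * table(lab2)) <= 1))
  expect_identical(split_stratified(labels, seed = 4), sp)
  expect_false(identical(split_stratified(labels, seed = 5)$train_idx,
                         sp$train_idx))
  expect_error(split_stratified(c("A", "A", "A", "A", "B", "B", "B")),
               "fewer than 4")
})

test_that("the trained ensemble carries six calibrated probabilistic learners", {
  fit <- small_fit()
  expect_identical(names(fit$model$learners),
                   c("svm", "rf", "nnet", "xgboost", "dectree", "knn"))
  expect_identical(fit$model$class_order, c("IA", "IE", "IS"))
  lg <- fit$log2
  feats <- prepare_features(lg, fit$model)
  probs <- predict_learner_probs(fit$model, feats$values)
  for (p in probs) {
    expect_identical(colnames(p), c("IA", "IE", "IS"))
    expect_true(all(p >= 0))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  }
})

test_that("ensemble probabilities equal the mean of the learner probabilities", {
  fit <- small_fit()
  feats <- prepare_features(fit$log2, fit$model)
  calls <- ensemble_predict(fit$model, feats$values)
  probs <- attr(calls, "learner_probs")
  manual <- (probs$svm + probs$rf + probs$nnet + probs$xgboost +
               probs$dectree + probs$knn) / 6
  ens <- as.matrix(calls[, c("P_IA", "P_IE", "P_IS")])
  dimnames(ens) <- dimnames(manual)
  expect_lt(max(abs(ens - manual)), 1e-12)
  expect_lt(max(abs(rowSums(ens) - 1)), 1e-9)
  # argmax labelling
  expect_identical(calls$label,
                   c("IA", "IE", "IS")[apply(manual, 1, which.max)])
})

test_that("ensemble separates planted subtypes on held-out samples", {
  fit <- small_fit()
  expect_gte(fit$report_valid$accuracy, 0.9)
  expect_gte(fit$report_valid$kappa, 0.85)
  expect_identical(sum(fit$report_valid$confusion), length(fit$split$valid_idx))
})

test_that("training is deterministic given data and seed", {
  fit <- small_fit()
  coh <- fit$cohort
  refit <- train_ensemble(fit$log2, coh$true_labels, fit$panel, seed = 11)
  feats <- prepare_features(fit$log2, fit$model)
  p1 <- ensemble_predict(fit$model, feats$values)
  p2 <- ensemble_predict(refit$model, feats$values)
  expect_identical(p1[, c("P_IA", "P_IE", "P_IS")],
                   p2[, c("P_IA", "P_IE", "P_IS")])
})

test_that("training validates panel coverage and class representation", {
  fit <- small_fit()
  coh <- fit$cohort
  bad_panel <- subtype_panel(list(IE = c(fit$panel$genes_by_subtype$IE, "NOT_A_GENE"),
                                  IS = fit$panel$genes_by_subtype$IS,
                                  IA = fit$panel$genes_by_subtype$IA))
  expect_error(train_ensemble(fit$log2, coh$true_labels, bad_panel, seed = 1),
               "NOT_A_GENE")
  two_class <- coh$true_labels
  two_class[two_class == "IS"] <- "IA"
  expect_error(train_ensemble(fit$log2, two_class, fit$panel, seed = 1),
               "three subtypes|3 subtype|fewer than 4")
})

test_that("validation accuracy does not improve as simulation noise grows", {
  accs <- vapply(c(0.2, 0.5, 1.0), function(ns) {
    coh <- simulate_cohort(small_spec(seed = 13, noise_sd = ns))
    planted <- split(names(coh$marker_map), coh$marker_map)
    sig_types <- tmesubtyper:::subtype_signature_types()
    panel <- subtype_panel(lapply(sig_types, function(tt) {
      unlist(planted[tt], use.names = FALSE)
    }))
    train_ensemble(to_log2(coh$expression), coh$true_labels, panel,
                   seed = 13)$report_valid$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.03))
})
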