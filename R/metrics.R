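# Agreement metrics for classification and clustering evaluation.

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with `p_e` computed
#' from the product of row and column marginals. In the degenerate case
#' `p_e = 1`, kappa is defined as 1 for perfect agreement and 0 otherwise
#' (with a warning).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_("label vectors differ in length")
  if (length(y_true) == 0L) stop_("empty label vectors")
  lev <- union(unique(as.character(y_true)), unique(as.character(y_pred)))
  tab <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps) {
    warn_("degenerate marginals (p_e = 1); kappa defined by convention")
    return(if (p_o == 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance;
#' invariant to label permutation.
#'
#' @param labels_a,labels_b equal-length partition vectors.
#' @return ARI (1 for identical partitions, ~0 for random agreement).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop_("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Classification report: confusion matrix, accuracy, kappa, per-class
#' precision and recall
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return A `classification_report` list.
#' @export
classification_report <- function(y_true, y_pred) {
  lev <- sort(union(unique(as.character(y_true)), unique(as.character(y_pred))))
  confusion <- table(truth = factor(y_true, levels = lev),
                     predicted = factor(y_pred, levels = lev))
  accuracy <- sum(diag(confusion)) / sum(confusion)
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(confusion = confusion, accuracy = accuracy,
                 kappa = cohens_kappa(y_true, y_pred),
                 precision = precision, recall = recall),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy: %.3f, kappa: %.3f\n", x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}
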