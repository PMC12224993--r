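# Estimation of the 23 TME cell features: 22 cell-type fractions by linear
# nu-support-vector regression against a signature matrix (relative mode:
# negative coefficients clipped, fractions normalized to sum 1), plus one
# fibroblast score computed as the mean log2 expression of fibroblast marker
# transcripts.

#' Read a signature matrix (genes x cell types) from TSV
#'
#' @param path TSV with gene symbols in the first column, cell-type labels in
#'   the header.
#' @return Numeric matrix, genes x cell types, uppercase gene rownames.
#' @export
read_signature_matrix <- function(path) {
  x <- read_expression(path, delimiter = "\t", scale_hint = "linear")
  m <- unclass(x)
  attr(m, "scale") <- NULL
  validate_signature(m)
}

validate_signature <- function(sig) {
  if (anyDuplicated(rownames(sig))) stop_("duplicate genes in signature matrix")
  if (any(sig < 0)) stop_("signature matrix must be non-negative")
  owns_max <- colSums(sig == matrixStats_rowMax(sig)) >= 1
  if (!all(owns_max)) {
    stop_("cell type(s) without any distinguishing marker: %s",
          paste(colnames(sig)[!owns_max], collapse = ", "))
  }
  sig
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMax <- function(x) apply(x, 1, max)

#' Marker mean score
#'
#' Per-sample score equal to the arithmetic mean of log2 expression over the
#' marker genes present in the matrix (the standard marker-mean abundance
#' estimator used for non-leukocyte populations such as fibroblasts).
#'
#' @param expr_log2 an [expression_matrix()] on log2 scale.
#' @param marker_genes character vector of marker symbols.
#' @return Named numeric vector of per-sample scores.
#' @export
marker_mean_score <- function(expr_log2, marker_genes) {
  if (expr_scale(expr_log2) != "log2") {
    stop_("marker_mean_score expects log2-scale expression")
  }
  marker_genes <- unique(toupper(marker_genes))
  present <- intersect(marker_genes, rownames(expr_log2))
  if (length(present) == 0L) {
    stop_("none of the requested marker genes are present: %s",
          paste(marker_genes, collapse = ", "))
  }
  if (length(present) < length(marker_genes)) {
    warn_("dropping %d absent marker gene(s): %s",
          length(marker_genes) - length(present),
          paste(setdiff(marker_genes, present), collapse = ", "))
  }
  colMeans(unclass(expr_log2)[present, , drop = FALSE])
}

#' Non-negative least squares deconvolution (reference method)
#'
#' Solves `min || S w - m ||` subject to `w >= 0` on the shared genes and
#' normalizes `w` to sum 1. Serves as the independent linear-mixing reference
#' against which the nu-SVR estimator is validated.
#'
#' @param mixture named numeric vector (one sample, linear scale).
#' @param signature genes x cell types matrix.
#' @return Named fraction vector summing to 1.
#' @export
nnls_deconvolve <- function(mixture, signature) {
  genes <- intersect(names(mixture), rownames(signature))
  if (length(genes) < 2L) stop_("too few shared genes for NNLS")
  w <- pracma::lsqnonneg(signature[genes, , drop = FALSE], mixture[genes])$x
  if (sum(w) == 0) stop_("degenerate mixture: all NNLS coefficients zero")
  stats::setNames(w / sum(w), colnames(signature))
}

#' nu-SVR cell-fraction deconvolution of one mixture sample
#'
#' Linear-kernel nu-support-vector regression of the mixture on the signature
#' columns, following the published SVR deconvolution algorithm: mixture and
#' signature are z-scored over shared genes, the model is fitted for each nu
#' in `nu_grid`, the fit with the lowest reconstruction root-mean-square
#' error is kept (ties broken toward the smallest nu), negative coefficients
#' are clipped to zero, and fractions are normalized to sum 1.
#'
#' @param mixture_sample named numeric vector of linear-scale expression.
#' @param signature genes x cell types non-negative matrix.
#' @param nu_grid candidate nu values.
#' @param min_shared minimum number of shared genes required.
#' @return Named fraction vector (one per signature column) summing to 1,
#'   with attributes `nu` (selected nu) and `rmse`.
#' @export
nusvr_deconvolve <- function(mixture_sample, signature,
                             nu_grid = c(0.25, 0.5, 0.75),
                             min_shared = 50L) {
  genes <- intersect(names(mixture_sample), rownames(signature))
  if (length(genes) < min_shared) {
    stop_("only %d genes shared between mixture and signature (need >= %d)",
          length(genes), min_shared)
  }
  X <- signature[genes, , drop = FALSE]
  y <- mixture_sample[genes]
  # whole-matrix standardization preserves relative column magnitudes
  X <- (X - mean(X)) / stats::sd(as.vector(X))
  y <- (y - mean(y)) / stats::sd(y)

  best <- NULL
  for (nu in sort(nu_grid)) {
    fit <- e1071::svm(X, y, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    w[w < 0] <- 0
    if (sum(w) == 0) next
    frac <- w / sum(w)
    rmse <- sqrt(mean((as.vector(X %*% frac) - y)^2))
    if (is.null(best) || rmse < best$rmse - 1e-12) {
      best <- list(frac = frac, rmse = rmse, nu = nu)
    }
  }
  if (is.null(best)) stop_("degenerate mixture: all SVR coefficients zero")
  out <- stats::setNames(best$frac, colnames(signature))
  attr(out, "nu") <- best$nu
  attr(out, "rmse") <- best$rmse
  out
}

#' Build the samples x 23 TME cell-feature matrix
#'
#' For every sample, 22 cell-type fractions are estimated by
#' [nusvr_deconvolve()] and one fibroblast feature by [marker_mean_score()].
#' Each of the 23 features is then independently z-scored across samples
#' (fractions on the 0-1 scale and the log2-scale fibroblast score are
#' otherwise incommensurable for clustering); constant features become
#' all-zero columns with a warning.
#'
#' @param expr an [expression_matrix()] (any scale; converted as needed).
#' @param signature genes x 22 cell-type signature matrix (linear scale).
#' @param fibroblast_markers marker symbols for the fibroblast score.
#' @param nu_grid passed to [nusvr_deconvolve()].
#' @return A `cell_fraction_profile`: list with `raw` and `standardized`
#'   (samples x 23 matrices), `feature_ids` and `sample_ids`.
#' @export
build_cell_feature_matrix <- function(expr, signature, fibroblast_markers,
                                      nu_grid = c(0.25, 0.5, 0.75)) {
  lin <- to_linear(expr)
  lg2 <- to_log2(expr)
  fractions <- t(apply(unclass(lin), 2, nusvr_deconvolve,
                       signature = signature, nu_grid = nu_grid))
  fib <- marker_mean_score(lg2, fibroblast_markers)
  raw <- cbind(fractions, Fibroblasts = fib)
  standardized <- zscore_cols(raw)
  structure(list(sample_ids = rownames(raw), feature_ids = colnames(raw),
                 raw = raw, standardized = standardized),
            class = "cell_fraction_profile")
}

#' @export
print.cell_fraction_profile <- function(x, ...) {
  cat(sprintf("cell_fraction_profile: %d samples x %d features\n",
              nrow(x$raw), ncol(x$raw)))
  invisible(x)
}

#' Write a cell-fraction profile to TSV
#'
#' @param profile a `cell_fraction_profile`.
#' @param path output TSV path.
#' @param which `"raw"` or `"standardized"`.
#' @return `path`, invisibly.
#' @export
write_cell_features <- function(profile, path, which = c("raw", "standardized")) {
  which <- match.arg(which)
  m <- profile[[which]]
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
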