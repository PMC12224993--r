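#' Construct an expression matrix container
#'
#' The universal carrier for bulk expression data: a numeric genes x samples
#' matrix with uppercase, unique gene symbols as rownames, sample ids as
#' colnames, and a declared measurement scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param scale one of `"counts"`, `"linear"`, `"log2"`. Raw counts and
#'   linear-scale intensities must be non-negative.
#' @return An object of class `expression_matrix` (the matrix with a
#'   `scale` attribute).
#' @export
expression_matrix <- function(values, scale = c("linear", "counts", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_("expression values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) stop_("empty expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_("expression matrix requires gene rownames and sample colnames")
  }
  if (anyNA(values)) stop_("expression matrix contains missing values")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) stop_("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values))) stop_("duplicate sample ids in expression matrix")
  if (scale %in% c("counts", "linear") && any(values < 0)) {
    stop_("negative values are not allowed on scale '%s'", scale)
  }
  structure(values, scale = scale, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  attr(m, "scale") <- NULL
  out <- if (missing(i) && missing(j)) m
  else if (missing(i)) m[, j, drop = drop]
  else if (missing(j)) m[i, , drop = drop]
  else m[i, j, drop = drop]
  if (is.matrix(out)) expression_matrix(out, scale = expr_scale(x)) else out
}

#' Measurement scale of an expression matrix
#' @param x an `expression_matrix`.
#' @return `"counts"`, `"linear"` or `"log2"`.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "linear"

#' Convert an expression matrix to log2 scale
#'
#' Counts/linear values are transformed as `log2(x + 1)`; log2 input is
#' returned unchanged.
#'
#' @param x an `expression_matrix` or plain matrix (assumed linear).
#' @return An `expression_matrix` on log2 scale.
#' @export
to_log2 <- function(x) {
  sc <- expr_scale(x)
  if (sc == "log2") return(x)
  expression_matrix(log2(unclass(x) + 1), scale = "log2")
}

#' Convert an expression matrix to linear scale
#'
#' Log2 values are back-transformed as `2^x - 1`; counts/linear input is
#' returned unchanged (counts are relabelled linear).
#'
#' @param x an `expression_matrix`.
#' @return An `expression_matrix` on linear scale.
#' @export
to_linear <- function(x) {
  sc <- expr_scale(x)
  v <- unclass(x)
  if (sc == "log2") v <- pmax(2^v - 1, 0)
  expression_matrix(v, scale = "linear")
}
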