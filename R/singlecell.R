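# Single-cell path: QC filtering, pseudobulk aggregation for bulk-trained
# classification, and per-cell subtype-signature scoring.

#' Quality-control filtering of single-cell counts
#'
#' Genes detected in fewer than `min_cells_per_gene` cells are removed
#' first; cells are then filtered by total UMIs, detected genes and
#' mitochondrial fraction (computed after gene filtering).
#'
#' @param sc a [single_cell_counts()] object.
#' @param min_umi minimum total UMI count per cell.
#' @param min_genes minimum detected genes per cell.
#' @param max_mito maximum mitochondrial count fraction (exclusive).
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param mito_prefix rowname prefix identifying mitochondrial genes.
#' @return A filtered [single_cell_counts()] with a `qc_report` attribute.
#' @export
qc_filter_cells <- function(sc, min_umi = 500, min_genes = 100,
                            max_mito = 0.25, min_cells_per_gene = 10,
                            mito_prefix = "MT-") {
  stopifnot(inherits(sc, "single_cell_counts"))
  counts <- sc$counts
  gene_cells <- Matrix::rowSums(counts > 0)
  counts <- counts[gene_cells >= min_cells_per_gene, , drop = FALSE]
  if (nrow(counts) == 0L) stop_("all genes removed by the detection filter")

  umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_genes <- startsWith(rownames(counts), toupper(mito_prefix))
  mito_frac <- if (any(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(umi, 1)
  } else rep(0, ncol(counts))
  keep <- umi >= min_umi & n_genes >= min_genes & mito_frac < max_mito
  if (!any(keep)) stop_("all cells removed by QC filters")
  counts <- counts[, keep, drop = FALSE]
  out <- single_cell_counts(counts, sc$cell_sample[colnames(counts)])
  attr(out, "qc_report") <- list(
    genes_removed = sum(gene_cells < min_cells_per_gene),
    cells_removed = sum(!keep), cells_kept = sum(keep),
    thresholds = list(min_umi = min_umi, min_genes = min_genes,
                      max_mito = max_mito,
                      min_cells_per_gene = min_cells_per_gene))
  out
}

#' Pseudobulk aggregation of single-cell counts
#'
#' Sums gene counts over the cells of each sample, then normalizes each
#' pseudobulk profile to counts-per-million and transforms to
#' `log2(CPM + 1)`.
#'
#' @param sc a [single_cell_counts()] with a complete cell-to-sample map.
#' @return A log2-scale [expression_matrix()], genes x samples. Samples
#'   with zero cells are dropped with a warning.
#' @export
pseudobulk_aggregate <- function(sc) {
  stopifnot(inherits(sc, "single_cell_counts"))
  if (is.null(sc$cell_sample)) {
    stop_("pseudobulk aggregation requires a cell-to-sample assignment")
  }
  samp <- factor(sc$cell_sample[colnames(sc$counts)])
  empty <- setdiff(unique(sc$cell_sample), levels(droplevels(samp)))
  if (length(empty)) warn_("dropping sample(s) with no cells: %s",
                           paste(empty, collapse = ", "))
  ind <- Matrix::sparseMatrix(i = seq_along(samp), j = as.integer(samp),
                              x = 1, dims = c(length(samp), nlevels(samp)),
                              dimnames = list(NULL, levels(samp)))
  agg <- as.matrix(sc$counts %*% ind)
  cpm <- sweep(agg, 2, pmax(colSums(agg), 1), "/") * 1e6
  expression_matrix(log2(cpm + 1), scale = "log2")
}

#' Log-normalize single-cell counts
#'
#' Per cell: counts scaled to `scale_factor` total, then `log2(x + 1)` —
#' the standard normalization preceding per-cell signature scoring.
#'
#' @param sc a [single_cell_counts()] object.
#' @param scale_factor per-cell library-size target.
#' @return Sparse genes x cells matrix of log-normalized expression.
#' @export
lognormalize_cells <- function(sc, scale_factor = 1e4) {
  stopifnot(inherits(sc, "single_cell_counts"))
  totals <- pmax(Matrix::colSums(sc$counts), 1)
  norm <- sc$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log2(norm@x + 1)
  dimnames(norm) <- dimnames(sc$counts)
  norm
}

#' Per-cell subtype-signature scores
#'
#' For each gene set, the per-cell score is the mean over set genes of the
#' gene-wise z-scored (across cells) log-normalized expression. Genes absent
#' from the matrix are dropped per set with a warning; genes constant across
#' cells contribute 0.
#'
#' @param sc_log genes x cells log-normalized matrix (e.g. from
#'   [lognormalize_cells()]).
#' @param subtype_sets a `gene_set_collection` (e.g. from
#'   [top_subtype_sets()] or [read_gene_sets()]).
#' @return A `cell_score_table` data.frame: `barcode` plus one score column
#'   per set.
#' @export
score_cells <- function(sc_log, subtype_sets) {
  stopifnot(inherits(subtype_sets, "gene_set_collection"))
  genes <- rownames(sc_log)
  n_cells <- ncol(sc_log)
  scores <- matrix(0, nrow = n_cells, ncol = length(subtype_sets$sets),
                   dimnames = list(colnames(sc_log), names(subtype_sets$sets)))
  for (nm in names(subtype_sets$sets)) {
    set <- subtype_sets$sets[[nm]]
    present <- intersect(set, genes)
    if (length(present) == 0L) {
      stop_("gene set '%s' has no genes present in the matrix", nm)
    }
    if (length(present) < length(set)) {
      warn_("set '%s': dropping %d absent gene(s)", nm,
            length(set) - length(present))
    }
    sub <- as.matrix(sc_log[present, , drop = FALSE])
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    flat <- sdv == 0
    sdv[flat] <- 1
    z <- (sub - mu) / sdv
    z[flat, ] <- 0  # constant genes contribute 0
    scores[, nm] <- colMeans(z)
  }
  out <- data.frame(barcode = rownames(scores), scores, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("cell_score_table", "data.frame")
  out
}
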