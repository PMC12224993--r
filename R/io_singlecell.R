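#' Construct a single-cell counts container
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes x cells,
#'   with gene rownames and barcode colnames.
#' @param cell_sample optional named character vector mapping barcode to
#'   sample id; required before pseudobulk aggregation.
#' @return A `single_cell_counts` object.
#' @export
single_cell_counts <- function(counts, cell_sample = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) {
    stop_("single-cell counts must be non-negative integers")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_("counts require gene rownames and barcode colnames")
  }
  rownames(counts) <- toupper(rownames(counts))
  if (!is.null(cell_sample)) {
    missing <- setdiff(colnames(counts), names(cell_sample))
    if (length(missing)) {
      stop_("%d barcodes lack a sample assignment (first: %s)",
            length(missing), missing[1L])
    }
    cell_sample <- cell_sample[colnames(counts)]
  }
  structure(list(counts = counts, cell_sample = cell_sample),
            class = "single_cell_counts")
}

#' @export
print.single_cell_counts <- function(x, ...) {
  cat(sprintf("single_cell_counts: %d genes x %d cells, %s samples\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$cell_sample)) "unassigned" else
                length(unique(x$cell_sample))))
  invisible(x)
}

#' Read 10x-style Matrix Market triplets
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally with
#' `.gz` suffix) in `dir_path`. Features may carry one or more columns; the
#' gene symbol is taken from the last of the first two columns present
#' (10x convention: id, symbol).
#'
#' @param dir_path directory containing the triplet files.
#' @param sample_map optional data.frame (barcode, sample) or named vector
#'   assigning each barcode to a sample.
#' @return A [single_cell_counts()] object.
#' @export
read_mtx <- function(dir_path, sample_map = NULL) {
  find1 <- function(base) {
    for (cand in file.path(dir_path, c(base, paste0(base, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
    stop_("missing %s(.gz) in %s", base, dir_path)
  }
  mtx <- find1("matrix.mtx")
  feat <- find1("features.tsv")
  bc <- find1("barcodes.tsv")
  m <- methods::as(Matrix::readMM(mtx), "generalMatrix")
  fdf <- utils::read.table(feat, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  genes <- if (ncol(fdf) >= 2L) fdf[[2L]] else fdf[[1L]]
  barcodes <- readLines(bc)
  if (nrow(m) != length(genes)) {
    stop_("MTX header declares %d genes but features.tsv lists %d",
          nrow(m), length(genes))
  }
  if (ncol(m) != length(barcodes)) {
    stop_("MTX header declares %d cells but barcodes.tsv lists %d",
          ncol(m), length(barcodes))
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(vals != round(vals))) stop_("non-integer entry in %s", mtx)
  genes <- make.unique(toupper(genes))
  dimnames(m) <- list(genes, barcodes)
  cs <- NULL
  if (!is.null(sample_map)) {
    cs <- if (is.data.frame(sample_map)) {
      stats::setNames(as.character(sample_map[[2L]]), sample_map[[1L]])
    } else sample_map
  }
  single_cell_counts(m, cell_sample = cs)
}

#' Write single-cell counts as a Matrix Market triplet directory
#'
#' @param sc a [single_cell_counts()] object.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_mtx <- function(sc, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(sc$counts, "generalMatrix"),
                  file.path(dir_path, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(sc$counts), symbol = rownames(sc$counts)),
    file.path(dir_path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sc$counts), file.path(dir_path, "barcodes.tsv"))
  if (!is.null(sc$cell_sample)) {
    utils::write.table(
      data.frame(barcode = names(sc$cell_sample), sample = sc$cell_sample),
      file.path(dir_path, "sample_map.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir_path)
}
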