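#' Read a bulk expression matrix from TSV/CSV
#'
#' Expects gene symbols in the first column and a header row of sample ids.
#' Gene symbols are uppercased at ingestion. Duplicate symbols are collapsed
#' to the row with the highest mean expression (one warning per collapsed
#' symbol), the common convention for microarray probe collapse.
#'
#' @param path file path.
#' @param delimiter field separator; `"\t"` (default) or `","`. Files ending
#'   in `.csv` default to comma.
#' @param scale_hint declared scale of the stored values
#'   (`"linear"`, `"counts"` or `"log2"`).
#' @param alias_map optional two-column data.frame (`from`, `to`) translating
#'   input symbols (e.g. mouse orthologs) before uppercasing/matching.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = NULL,
                            scale_hint = c("linear", "counts", "log2"),
                            alias_map = NULL) {
  scale_hint <- match.arg(scale_hint)
  if (!file.exists(path)) stop_("expression file not found: %s", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop_("empty expression matrix in %s", path)
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  samples <- colnames(vals)
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop_("non-numeric expression value '%s' for gene %s, sample %s",
            col[bad], genes[bad], samples[j])
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_("missing expression value for gene %s, sample %s",
          genes[idx[1L]], samples[idx[2L]])
  }
  if (!is.null(alias_map)) {
    stopifnot(ncol(alias_map) >= 2L)
    map <- stats::setNames(toupper(alias_map[[2L]]), toupper(alias_map[[1L]]))
    hit <- toupper(genes) %in% names(map)
    genes[hit] <- map[toupper(genes[hit])]
  }
  genes <- toupper(genes)
  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    keep <- rep(TRUE, length(genes))
    for (g in unique(genes[duplicated(genes)])) {
      idx <- which(genes == g)
      best <- idx[which.max(means[idx])]
      keep[setdiff(idx, best)] <- FALSE
      warn_("collapsed %d duplicate rows of gene %s to the highest-mean row",
            length(idx), g)
    }
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(m) <- genes
  colnames(m) <- samples
  expression_matrix(m, scale = scale_hint)
}

#' Write a bulk expression matrix to TSV/CSV
#'
#' @param x an [expression_matrix()] (or plain named matrix).
#' @param path output file path; `.csv` suffix selects comma separation.
#' @param delimiter field separator; inferred from the suffix when `NULL`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = NULL) {
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
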