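#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene1 TAB gene2
#' ...`. Gene symbols are uppercased; duplicates within a set are removed
#' preserving first occurrence.
#'
#' @param path GMT file path (optionally gzipped).
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop_("GMT line with fewer than 3 fields: '%s'", ln)
    nm <- parts[1L]
    if (nm %in% names(sets)) stop_("duplicate gene-set name in GMT: %s", nm)
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop_("gene set %s is empty", nm)
    sets[[nm]] <- genes
    descs[nm] <- parts[2L]
  }
  if (length(sets) == 0L) stop_("no gene sets found in %s", path)
  structure(list(sets = sets, descriptions = descs),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%s)\n", length(x$sets),
              paste(sprintf("%s: %d", names(x$sets), lengths(x$sets)),
                    collapse = ", ")))
  invisible(x)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a `gene_set_collection` or a named list of gene vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gsc, path) {
  if (inherits(gsc, "gene_set_collection")) {
    sets <- gsc$sets
    descs <- gsc$descriptions
  } else {
    sets <- gsc
    descs <- stats::setNames(rep("", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
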