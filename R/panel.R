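# Subtype feature-gene panel selection: pairwise Wilcoxon differential
# expression with Benjamini-Hochberg correction, removal of genes shared
# between subtypes, then random-forest permutation-importance reduction.

#' Pairwise differential expression between the three subtypes
#'
#' For every gene and every ordered subtype pair, a two-sided Wilcoxon
#' rank-sum p-value and the log2 fold change of group means are computed;
#' p-values are Benjamini-Hochberg adjusted across genes within each
#' comparison. A gene enters a subtype's up-list iff it is significant
#' (`adjusted_p < alpha`) with `log2_fold_change >= min_lfc` against BOTH
#' other subtypes.
#'
#' @param expr_log2 an [expression_matrix()] on log2 scale.
#' @param subtype_labels named vector of IE/IS/IA labels (names = sample ids).
#' @param alpha BH-adjusted significance threshold.
#' @param min_lfc minimum log2 fold change.
#' @return A `deg_result`: list with `table` (data.frame gene, subtype,
#'   comparison, log2_fold_change, p_value, adjusted_p) and `up_lists`
#'   (named list IE/IS/IA of up-regulated genes).
#' @export
pairwise_degs <- function(expr_log2, subtype_labels, alpha = 0.05,
                          min_lfc = 1.0) {
  if (expr_scale(expr_log2) != "log2") {
    stop_("pairwise_degs expects log2-scale expression (use to_log2())")
  }
  m <- unclass(expr_log2)[, names(subtype_labels), drop = FALSE]
  groups <- sort(unique(subtype_labels))
  if (length(groups) != 3L) stop_("expected 3 subtype groups, got %d",
                                  length(groups))
  sizes <- table(subtype_labels)
  if (any(sizes < 3L)) {
    stop_("subtype group(s) with fewer than 3 samples: %s",
          paste(names(sizes)[sizes < 3L], collapse = ", "))
  }
  idx <- lapply(groups, function(g) which(subtype_labels == g))
  names(idx) <- groups
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  rows <- list()
  for (pr in pairs) {
    a <- idx[[pr[1L]]]; b <- idx[[pr[2L]]]
    pv <- apply(m, 1, function(x) {
      stats::wilcox.test(x[a], x[b], exact = FALSE)$p.value
    })
    pv[is.na(pv)] <- 1  # constant genes: no evidence
    lfc <- rowMeans(m[, a, drop = FALSE]) - rowMeans(m[, b, drop = FALSE])
    adj <- stats::p.adjust(pv, method = "BH")
    cmp <- paste(pr[1L], "vs", pr[2L])
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rownames(m), subtype = pr[1L], comparison = cmp,
      log2_fold_change = lfc, p_value = pv, adjusted_p = adj,
      row.names = NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rownames(m), subtype = pr[2L], comparison = paste(pr[2L], "vs", pr[1L]),
      log2_fold_change = -lfc, p_value = pv, adjusted_p = adj,
      row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  up_lists <- lapply(groups, function(g) {
    sub <- tab[tab$subtype == g, ]
    hit <- sub$adjusted_p < alpha & sub$log2_fold_change >= min_lfc
    counts <- table(sub$gene[hit])
    sort(names(counts)[counts == 2L])  # up vs BOTH other subtypes
  })
  names(up_lists) <- groups
  structure(list(table = tab, up_lists = up_lists,
                 alpha = alpha, min_lfc = min_lfc),
            class = "deg_result")
}

#' Remove genes shared between subtype up-lists
#'
#' Any gene appearing in two or more of the three lists is removed from all
#' of them; the output lists are pairwise disjoint. Idempotent.
#'
#' @param up_lists named list of three gene vectors.
#' @return Named list of disjoint gene vectors.
#' @export
remove_common <- function(up_lists) {
  stopifnot(length(up_lists) == 3L)
  all_genes <- unlist(up_lists, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  lapply(up_lists, function(g) setdiff(g, shared))
}

#' Random-forest importance reduction of candidate panel genes
#'
#' Fits a random-forest classifier of subtype on the candidate genes and
#' retains genes whose permutation importance (mean decrease in accuracy)
#' exceeds the mean importance; retained genes keep their subtype
#' assignment.
#'
#' @param expr_log2 an [expression_matrix()] on log2 scale.
#' @param subtype_labels named IE/IS/IA label vector.
#' @param candidate_lists named list of disjoint per-subtype candidate genes.
#' @param trees number of trees.
#' @param seed RNG seed (recorded in provenance).
#' @return A `subtype_panel`: list with `genes_by_subtype` and `provenance`.
#' @export
rf_reduce <- function(expr_log2, subtype_labels, candidate_lists,
                      trees = 1000, seed = 1) {
  cand <- unlist(candidate_lists, use.names = FALSE)
  if (anyDuplicated(cand)) stop_("candidate lists must be disjoint")
  if (length(cand) < 2L) stop_("need at least 2 candidate genes")
  m <- unclass(expr_log2)
  missing <- setdiff(cand, rownames(m))
  if (length(missing)) stop_("candidate gene(s) absent from expression: %s",
                             paste(missing, collapse = ", "))
  x <- t(m[cand, names(subtype_labels), drop = FALSE])
  y <- factor(subtype_labels)
  fit <- with_seed_(seed, {
    randomForest::randomForest(x, y, ntree = trees, importance = TRUE)
  })
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1L]
  if (all(imp <= 0)) stop_("no informative genes: all importances <= 0")
  keep <- names(imp)[imp > mean(imp)]
  genes_by_subtype <- lapply(candidate_lists, function(g) intersect(g, keep))
  subtype_panel(genes_by_subtype,
                provenance = list(rule = "permutation importance > mean",
                                  trees = trees, seed = seed,
                                  n_candidates = length(cand),
                                  importance = imp))
}

#' Construct a subtype panel
#'
#' @param genes_by_subtype named list (IE, IS, IA) of disjoint gene vectors.
#' @param provenance optional list of selection parameters.
#' @return A `subtype_panel` object.
#' @export
subtype_panel <- function(genes_by_subtype, provenance = list()) {
  genes_by_subtype <- lapply(genes_by_subtype, function(g) unique(toupper(g)))
  all_genes <- unlist(genes_by_subtype, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop_("panel lists must be pairwise disjoint")
  structure(list(genes_by_subtype = genes_by_subtype, provenance = provenance),
            class = "subtype_panel")
}

#' @export
print.subtype_panel <- function(x, ...) {
  n <- lengths(x$genes_by_subtype)
  cat(sprintf("subtype_panel: %s (total %d genes)\n",
              paste(names(n), n, sep = ": ", collapse = ", "), sum(n)))
  invisible(x)
}

#' All genes of a panel in fixed order
#' @param panel a `subtype_panel`.
#' @return Character vector (IE genes, then IS, then IA, in stored order).
#' @export
panel_genes <- function(panel) unlist(panel$genes_by_subtype, use.names = FALSE)

#' Full panel selection pipeline
#'
#' Pairwise DEGs, removal of shared genes, then random-forest reduction.
#'
#' @inheritParams pairwise_degs
#' @inheritParams rf_reduce
#' @return A `subtype_panel`.
#' @export
select_panel <- function(expr_log2, subtype_labels, alpha = 0.05,
                         min_lfc = 1.0, trees = 1000, seed = 1) {
  degs <- pairwise_degs(expr_log2, subtype_labels, alpha = alpha,
                        min_lfc = min_lfc)
  cand <- remove_common(degs$up_lists)
  panel <- rf_reduce(expr_log2, subtype_labels, cand, trees = trees,
                     seed = seed)
  panel$provenance$alpha <- alpha
  panel$provenance$min_lfc <- min_lfc
  panel
}

#' Top up-regulated genes per subtype as a gene-set collection
#'
#' Ranks each subtype's up-list by the worse (larger) of its two adjusted
#' p-values, then by the smaller log2 fold change, and keeps the top `n`
#' genes; the resulting sets drive per-cell subtype-signature scoring.
#'
#' @param degs a `deg_result` from [pairwise_degs()].
#' @param n genes kept per subtype.
#' @return A `gene_set_collection` with sets `TME_IE`, `TME_IS`, `TME_IA`.
#' @export
top_subtype_sets <- function(degs, n = 100) {
  stopifnot(inherits(degs, "deg_result"))
  sets <- lapply(names(degs$up_lists), function(g) {
    genes <- degs$up_lists[[g]]
    sub <- degs$table[degs$table$subtype == g & degs$table$gene %in% genes, ]
    worst_p <- tapply(sub$adjusted_p, sub$gene, max)
    min_lfc <- tapply(sub$log2_fold_change, sub$gene, min)
    ord <- order(worst_p[genes], -min_lfc[genes])
    utils::head(genes[ord], n)
  })
  names(sets) <- paste0("TME_", names(degs$up_lists))
  sets <- sets[lengths(sets) > 0L]
  structure(list(sets = sets,
                 descriptions = stats::setNames(
                   rep("top subtype-upregulated genes", length(sets)),
                   names(sets))),
            class = "gene_set_collection")
}
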