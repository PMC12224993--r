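# Application of a trained ensemble to new bulk cohorts: gene alignment,
# cohort-wise normalization, missing-gene imputation, coverage diagnostics
# and the merged IE/IS reporting policy for panels with poor coverage.

#' Align and normalize a new cohort onto a model's feature space
#'
#' Panel genes are z-scored within the new cohort (cohort-wise statistics by
#' default, which makes the classifier robust to platform shifts between
#' microarray, RNA-seq and targeted panels); genes absent from the cohort
#' are imputed as 0, i.e. the cohort mean after z-scoring. With
#' `use_train_stats = TRUE` the model's stored training statistics are used
#' instead (strict reuse mode, also the only mode allowed for cohorts of
#' fewer than 3 samples).
#'
#' @param expr an [expression_matrix()] (any scale; converted to log2).
#' @param model a `tme_ensemble`.
#' @param use_train_stats z-score with training statistics instead of
#'   cohort statistics.
#' @param min_total_coverage minimum fraction of panel genes that must be
#'   present.
#' @return An `aligned_features` list: `values` (samples x panel genes,
#'   z-scored), `coverage_by_subtype`, `coverage`, `imputed_genes`.
#' @export
prepare_features <- function(expr, model, use_train_stats = FALSE,
                             min_total_coverage = 0.4) {
  m <- unclass(to_log2(expr))
  genes <- model$gene_order
  present <- intersect(genes, rownames(m))
  coverage <- length(present) / length(genes)
  if (coverage < min_total_coverage) {
    stop_("only %.0f%% of panel genes present (minimum %.0f%%)",
          100 * coverage, 100 * min_total_coverage)
  }
  if (ncol(m) < 3L && !use_train_stats) {
    stop_("cohort z-scoring undefined for fewer than 3 samples; use use_train_stats = TRUE")
  }
  x <- matrix(0, nrow = ncol(m), ncol = length(genes),
              dimnames = list(colnames(m), genes))
  sub <- t(m[present, , drop = FALSE])
  if (use_train_stats) {
    mu <- model$feature_stats$mean[match(present, genes)]
    sdv <- model$feature_stats$sd[match(present, genes)]
    x[, present] <- sweep(sweep(sub, 2, mu, "-"), 2, sdv, "/")
  } else {
    x[, present] <- zscore_cols(sub, warn = FALSE)
  }
  cov_by <- vapply(model$panel$genes_by_subtype, function(g) {
    if (length(g) == 0L) return(1)
    mean(g %in% present)
  }, numeric(1))
  structure(list(values = x, coverage = coverage,
                 coverage_by_subtype = cov_by,
                 imputed_genes = setdiff(genes, present)),
            class = "aligned_features")
}

#' Classify a bulk cohort into TME subtypes
#'
#' Runs [prepare_features()] then [ensemble_predict()]. If any subtype's
#' panel coverage falls below `min_subtype_coverage` (and merging is
#' enabled), a `merged_label` column collapses the two
#' immunotherapy-resistant subtypes into an "IE/IS" group — the reporting
#' policy for targeted platforms that lack part of the panel.
#'
#' @param expr an [expression_matrix()].
#' @param model a `tme_ensemble`.
#' @param merge_low_coverage enable the merged IE/IS reporting policy.
#' @param min_subtype_coverage per-subtype coverage threshold triggering it.
#' @param use_train_stats passed to [prepare_features()].
#' @return A `subtype_calls` data.frame with added `coverage` and
#'   `low_coverage` columns (and `merged_label` when triggered), plus the
#'   `aligned_features` in attribute `features`.
#' @export
classify_cohort <- function(expr, model, merge_low_coverage = TRUE,
                            min_subtype_coverage = 0.6,
                            use_train_stats = FALSE) {
  feats <- prepare_features(expr, model, use_train_stats = use_train_stats)
  calls <- ensemble_predict(model, feats$values)
  calls$coverage <- feats$coverage
  low <- any(feats$coverage_by_subtype < min_subtype_coverage)
  calls$low_coverage <- low
  if (low && merge_low_coverage) {
    calls$merged_label <- ifelse(calls$label %in% c("IE", "IS"), "IE/IS", "IA")
  }
  attr(calls, "features") <- feats
  calls
}

#' Write subtype calls to TSV
#'
#' @param calls a `subtype_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
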