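# Resampling consensus clustering of the standardized cell-feature matrix,
# PAC-based selection of k, and phenotype-driven naming of the three
# clusters as IE / IS / IA.

#' Resampling consensus clustering
#'
#' For each repeat, a fraction of samples is drawn without replacement and
#' partitioned by the base clusterer for every candidate k. The consensus
#' matrix entry (i, j) is the proportion of co-clustering among the repeats
#' in which both samples were drawn. Final labels for each k come from an
#' average-linkage hierarchical cut of `1 - consensus`.
#'
#' @param features standardized samples x features matrix (rownames =
#'   sample ids).
#' @param k_values candidate cluster numbers.
#' @param reps number of resampling repeats.
#' @param subsample_fraction fraction of samples drawn per repeat, in (0, 1].
#' @param base base clusterer: `"kmeans"` (10 restarts per repeat) or
#'   `"hclust"` (Ward linkage on Euclidean distance).
#' @param seed base seed; repeat r uses `seed + r`.
#' @return A `consensus_result`: list with `k_values`, `consensus` (named
#'   list of samples x samples matrices), `pac`, `labels`, `reps`,
#'   `subsample_fraction`, `seed`.
#' @export
consensus_cluster <- function(features, k_values = 2:6, reps = 1000,
                              subsample_fraction = 0.8,
                              base = c("kmeans", "hclust"), seed = 1) {
  base <- match.arg(base)
  if (inherits(features, "cell_fraction_profile")) features <- features$standardized
  assert_finite_matrix(features, "feature matrix")
  n <- nrow(features)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop_("subsample_fraction must be in (0, 1]")
  }
  if (max(k_values) > n) stop_("k = %d exceeds the number of samples (%d)",
                               max(k_values), n)
  if (n < max(k_values) * 3L) {
    stop_("need at least 3 samples per candidate cluster (have %d for k = %d)",
          n, max(k_values))
  }
  ids <- rownames(features) %||% sprintf("S%d", seq_len(n))
  # canonical (sorted-id) processing order makes the result exactly
  # invariant to the input sample order; results are mapped back at the end
  ord <- order(ids)
  features <- features[ord, , drop = FALSE]
  ids_c <- ids[ord]
  m <- max(2L, floor(n * subsample_fraction))

  co_sampled <- matrix(0, n, n)
  co_clustered <- stats::setNames(
    lapply(k_values, function(k) matrix(0, n, n)), as.character(k_values))
  base_fit <- function(x, k) {
    if (base == "kmeans") {
      stats::kmeans(x, centers = k, nstart = 10)$cluster
    } else {
      stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k)
    }
  }
  for (r in seq_len(reps)) {
    with_seed_(seed + r, {
      idx <- sort(sample.int(n, m))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      for (k in k_values) {
        cl <- base_fit(features[idx, , drop = FALSE], k)
        ind <- stats::model.matrix(~ 0 + factor(cl))
        conn <- tcrossprod(ind)
        co_clustered[[as.character(k)]][idx, idx] <-
          co_clustered[[as.character(k)]][idx, idx] + conn
      }
    })
  }
  never <- co_sampled == 0
  diag(never) <- FALSE
  if (any(never)) {
    warn_("%d sample pairs were never co-sampled; their consensus is set to 0",
          sum(never) / 2)
  }
  denom <- co_sampled
  denom[denom == 0] <- 1

  back <- match(ids, ids_c)
  consensus <- list()
  labels <- list()
  pac <- stats::setNames(numeric(length(k_values)), as.character(k_values))
  for (k in k_values) {
    cm <- co_clustered[[as.character(k)]] / denom
    cm[never] <- 0
    diag(cm) <- 1
    dimnames(cm) <- list(ids_c, ids_c)
    lab <- stats::cutree(stats::hclust(stats::as.dist(1 - cm),
                                       method = "average"), k)
    cm <- cm[back, back]
    consensus[[as.character(k)]] <- cm
    labels[[as.character(k)]] <- stats::setNames(lab[back], ids)
    pac[as.character(k)] <- pac_statistic(cm)
  }
  structure(list(k_values = k_values, consensus = consensus, pac = pac,
                 labels = labels, reps = reps,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, %d reps, PAC: %s\n",
              paste(x$k_values, collapse = ", "), x$reps,
              paste(sprintf("%s=%.3f", names(x$pac), x$pac), collapse = ", ")))
  invisible(x)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of off-diagonal consensus entries falling strictly inside the
#' ambiguity band `(lower, upper)`; lower PAC indicates a more stable
#' partition.
#'
#' @param consensus samples x samples consensus matrix.
#' @param lower,upper ambiguity band bounds.
#' @return PAC value in \[0, 1\].
#' @export
pac_statistic <- function(consensus, lower = 0.1, upper = 0.9) {
  v <- consensus[upper.tri(consensus)]
  if (length(v) == 0L) stop_("PAC undefined for fewer than 2 samples")
  mean(v > lower & v < upper)
}

#' Select the number of clusters by minimal PAC
#'
#' @param result a `consensus_result`.
#' @return The k with the lowest PAC (ties go to the smaller k). A single
#'   candidate is returned with a warning since no comparison is possible.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  pac <- result$pac
  if (length(pac) == 0L || anyNA(pac)) stop_("PAC undefined for this result")
  if (length(pac) == 1L) {
    warn_("single candidate k = %s: no comparison possible", names(pac))
    return(as.integer(names(pac)))
  }
  ks <- as.integer(names(pac))
  ks[order(pac, ks)][1L]
}

#' Name three clusters as IE / IS / IA from infiltration phenotypes
#'
#' IA is the cluster with the highest mean standardized CD8 T-cell feature;
#' of the remaining two, IE is the one with the higher mean stromal
#' (fibroblast plus, when present, endothelial) feature, and IS is the last.
#'
#' @param labels per-sample cluster indices (exactly 3 distinct values).
#' @param profile a `cell_fraction_profile` (standardized features used).
#' @param cd8_feature,stromal_features feature names driving the rules.
#' @return A `subtype_labeling`: list with `subtype` (named IE/IS/IA vector)
#'   and `naming_evidence` (cluster x feature mean-z matrix).
#' @export
name_clusters <- function(labels, profile,
                          cd8_feature = "T_cells_CD8",
                          stromal_features = c("Fibroblasts",
                                               "Endothelial_cells")) {
  stopifnot(inherits(profile, "cell_fraction_profile"))
  z <- profile$standardized[names(labels) %||% rownames(profile$standardized), ,
                            drop = FALSE]
  cl <- sort(unique(labels))
  if (length(cl) != 3L) stop_("expected exactly 3 clusters, got %d", length(cl))
  if (!cd8_feature %in% colnames(z)) {
    stop_("CD8 feature '%s' absent from profile", cd8_feature)
  }
  stromal <- intersect(stromal_features, colnames(z))
  if (length(stromal) == 0L) stop_("no stromal feature present in profile")
  evidence <- t(vapply(cl, function(k) colMeans(z[labels == k, , drop = FALSE]),
                       numeric(ncol(z))))
  rownames(evidence) <- paste0("cluster_", cl)

  cd8 <- evidence[, cd8_feature]
  if (sum(cd8 == max(cd8)) > 1L) {
    stop_("exact tie on the CD8 feature; manual naming required")
  }
  ia <- cl[which.max(cd8)]
  rest <- setdiff(cl, ia)
  strom <- rowSums(evidence[paste0("cluster_", rest), stromal, drop = FALSE])
  if (strom[1L] == strom[2L]) {
    stop_("exact tie on the stromal feature; manual naming required")
  }
  ie <- rest[which.max(strom)]
  is_ <- setdiff(rest, ie)
  map <- stats::setNames(c("IA", "IE", "IS"), c(ia, ie, is_))
  subtype <- stats::setNames(unname(map[as.character(labels)]), names(labels))
  structure(list(sample_ids = names(labels), subtype = subtype,
                 naming_evidence = evidence,
                 cluster_map = map),
            class = "subtype_labeling")
}

#' @export
print.subtype_labeling <- function(x, ...) {
  tab <- table(x$subtype)
  cat(sprintf("subtype_labeling: %s\n",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
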