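# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, expr, envir = .fixtures)
  .fixtures[[name]]
}

# small cohort for unit tests: 60 samples, 200 genes, 3 markers/type
small_spec <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_genes = 200, markers_per_type = 3, n_per_subtype = 20, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# strip the container class/attributes for comparison with plain matrices
as_plain <- function(x) {
  m <- unclass(x)
  attr(m, "scale") <- NULL
  m
}

small_cohort <- function() memo("small_cohort", simulate_cohort(small_spec()))

small_signature <- function() memo("small_signature", {
  signature_from_cohort(small_cohort())
})

# panel + trained ensemble on the small cohort (true labels)
small_fit <- function() memo("small_fit", {
  coh <- small_cohort()
  lg <- to_log2(coh$expression)
  panel <- select_panel(lg, coh$true_labels, trees = 500, seed = 11)
  c(train_ensemble(lg, coh$true_labels, panel, seed = 11),
    list(panel = panel, log2 = lg, cohort = coh))
})

zscore_cols <- tmesubtyper:::zscore_cols

# independent brute-force oracles -------------------------------------------

# Cohen's kappa evaluated directly from a confusion matrix, summing cell by
# cell (independent of the package's table-based implementation)
kappa_bruteforce <- function(confusion) {
  n <- sum(confusion)
  p_o <- 0
  p_e <- 0
  for (i in seq_len(nrow(confusion))) {
    p_o <- p_o + confusion[i, i] / n
    p_e <- p_e + sum(confusion[i, ]) * sum(confusion[, i]) / n^2
  }
  (p_o - p_e) / (1 - p_e)
}

# ARI by explicit enumeration of all element pairs
ari_bruteforce <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# all partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(max(labels) + 1L)) grow(c(labels, v))
  }
  grow(1L)
  out
}

# A hand-constructed fixture with known QC outcomes: ten filler cells
# express every gene (keeping the gene-detection filter neutral) and each
# failing probe cell violates exactly one cell-level threshold, so the
# surviving set is fully determined.
qc_fixture <- function() {
  n_genes <- 120
  genes <- c(sprintf("GENE%03d", 1:(n_genes - 1)), "MT-CO1")
  make_cell <- function(umi, n_expressed, mito_frac) {
    x <- numeric(n_genes)
    mito <- round(umi * mito_frac)
    body <- umi - mito
    idx <- seq_len(n_expressed - (mito > 0))
    base <- rep(floor(body / length(idx)), length(idx))
    base[1] <- base[1] + body - sum(base)
    x[idx] <- base
    x[n_genes] <- mito
    x
  }
  fillers <- matrix(10, n_genes, 10,
                    dimnames = list(NULL, sprintf("filler%02d", 1:10)))
  probes <- cbind(
    good1 = make_cell(2000, 110, 0.05),
    good2 = make_cell(1500, 115, 0.10),
    good3 = make_cell(800, 105, 0.0),
    good4 = make_cell(5000, 119, 0.20),
    low_umi = make_cell(400, 110, 0.05),       # < 500 UMIs
    few_genes = make_cell(2000, 80, 0.05),     # < 100 genes
    high_mito = make_cell(2000, 110, 0.30),    # >= 25% mito
    edge_umi = make_cell(500, 105, 0.0),       # exactly 500: kept
    edge_genes = make_cell(1000, 100, 0.0),    # exactly 100 genes: kept
    edge_mito = make_cell(2000, 110, 0.25))    # exactly 25%: removed
  m <- Matrix::Matrix(cbind(fillers, probes), sparse = TRUE)
  rownames(m) <- genes
  single_cell_counts(m, stats::setNames(rep("S1", ncol(m)), colnames(m)))
}

qc_expected_survivors <- function() {
  c(sprintf("filler%02d", 1:10),
    "good1", "good2", "good3", "good4", "edge_umi", "edge_genes")
}

# planted 22-type fraction truth renormalized to the leukocyte columns
leukocyte_truth <- function(cohort, signature) {
  tr <- cohort$true_fractions[, colnames(signature), drop = FALSE]
  sweep(tr, 1, rowSums(tr), "/")
}
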