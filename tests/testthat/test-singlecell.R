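test_that("QC filters keep exactly the cells passing every threshold", {
  sc <- qc_fixture()
  out <- qc_filter_cells(sc)
  expect_setequal(colnames(out$counts), qc_expected_survivors())
  rep <- attr(out, "qc_report")
  expect_identical(rep$cells_removed, 4L)
  # gene filter runs first: genes seen in < 10 cells would be dropped
  gene_cells <- Matrix::rowSums(sc$counts > 0)
  expect_identical(nrow(out$counts), sum(gene_cells >= 10))
  expect_error(qc_filter_cells(sc, min_umi = 1e9), "all cells")
})

test_that("gene detection filter drops genes seen in too few cells", {
  m <- Matrix::Matrix(0, 3, 12, sparse = TRUE,
                      dimnames = list(c("G1", "G2", "G3"), sprintf("C%02d", 1:12)))
  m["G1", ] <- 600   # detected in 12 cells
  m["G2", 1:9] <- 600  # detected in 9 cells -> removed
  m["G3", 1:10] <- 600
  sc <- single_cell_counts(m, setNames(rep("S1", 12), colnames(m)))
  out <- qc_filter_cells(sc, min_genes = 1)
  expect_setequal(rownames(out$counts), c("G1", "G3"))
})

test_that("pseudobulk sums member cells and normalizes to log2 CPM", {
  coh <- small_cohort()
  cells <- simulate_cells(coh, cells_per_sample = 40,
                          samples = rownames(coh$true_fractions)[1:4])
  sc <- cells$sc
  pb <- pseudobulk_aggregate(sc)
  expect_identical(expr_scale(pb), "log2")
  expect_identical(sort(colnames(pb)), sort(unique(sc$cell_sample)))
  # raw aggregate equals the column sums of member cells
  s <- colnames(pb)[1]
  member <- names(sc$cell_sample)[sc$cell_sample == s]
  agg <- Matrix::rowSums(sc$counts[, member, drop = FALSE])
  cpm <- agg / sum(agg) * 1e6
  expect_equal(unname(unclass(pb)[, s]), unname(log2(cpm + 1)))
  # order invariance
  perm <- withr::with_seed(2, sample(ncol(sc$counts)))
  sc_perm <- single_cell_counts(sc$counts[, perm], sc$cell_sample[perm])
  pb2 <- pseudobulk_aggregate(sc_perm)
  expect_equal(as_plain(pb2)[, colnames(pb)], as_plain(pb))
})

test_that("a single-cell sample's pseudobulk equals that cell's log2 CPM", {
  m <- Matrix::Matrix(c(10, 30, 60), 3, 1, sparse = TRUE,
                      dimnames = list(c("G1", "G2", "G3"), "C1"))
  sc <- single_cell_counts(m, c(C1 = "S1"))
  pb <- pseudobulk_aggregate(sc)
  expect_equal(unname(unclass(pb)[, "S1"]),
               log2(c(10, 30, 60) / 100 * 1e6 + 1))
})

test_that("per-cell signature scores separate matching cell types", {
  coh <- small_cohort()
  cells <- simulate_cells(coh, cells_per_sample = 60,
                          samples = rownames(coh$true_fractions)[seq(1, 60, 6)])
  lg <- to_log2(coh$expression)
  degs <- pairwise_degs(lg, coh$true_labels)
  sets <- top_subtype_sets(degs, n = 100)
  scl <- lognormalize_cells(cells$sc)
  scores <- score_cells(scl, sets)
  ct <- cells$cell_types[scores$barcode]
  # T/NK-like cells score higher on the IA set than stromal cells
  expect_gt(mean(scores$TME_IA[ct == "T_cells_CD8"]),
            mean(scores$TME_IA[ct == "Fibroblasts"]))
  expect_gt(mean(scores$TME_IE[ct == "Fibroblasts"]),
            mean(scores$TME_IE[ct == "T_cells_CD8"]))
  expect_true(all(is.finite(as.matrix(scores[, -1]))))
})

test_that("score_cells handles single-gene sets, constant genes and absent sets", {
  m <- Matrix::Matrix(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5)), sparse = TRUE,
                      dimnames = list(c("G1", "G2"), sprintf("C%d", 1:4)))
  gsc <- structure(list(sets = list(one = "G1", flat = "G2"),
                        descriptions = c(one = "", flat = "")),
                   class = "gene_set_collection")
  sc <- score_cells(m, gsc)
  x <- as.numeric(m["G1", ])
  expect_equal(sc$one, (x - mean(x)) / sd(x))
  expect_equal(sc$flat, rep(0, 4))  # constant gene contributes 0
  gsc$sets$ghost <- "NOT_THERE"
  gsc$descriptions["ghost"] <- ""
  expect_error(score_cells(m, gsc), "ghost")
})

test_that("pseudobulk of synthetic cells recovers each sample's subtype", {
  fit <- small_fit()
  coh <- fit$cohort
  cells <- simulate_cells(coh, cells_per_sample = 250,
                          samples = rownames(coh$true_fractions)[seq(2, 60, 4)])
  pb <- pseudobulk_aggregate(qc_filter_cells(cells$sc))
  calls <- classify_cohort(pb, fit$model)
  expect_gte(mean(calls$label == coh$true_labels[calls$sample]), 0.9)
})
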