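make_blobs <- function(n_per = 20, sd = 0.01, seed = 3) {
  centers <- rbind(c(0, 0), c(10, 0), c(5, 8.66))
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
    }))
  })
  rownames(x) <- sprintf("B%02d", seq_len(nrow(x)))
  list(x = x, truth = rep(1:3, each = n_per))
}

test_that("well-separated blobs give binary consensus and PAC selects k = 3", {
  b <- make_blobs()
  cc <- consensus_cluster(b$x, k_values = 2:6, reps = 100, seed = 7)
  cm <- cc$consensus[["3"]]
  same <- outer(b$truth, b$truth, "==")
  expect_true(all(cm[same] == 1))
  expect_true(all(cm[!same] == 0))
  # definition invariants
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(unname(cc$pac["3"]), 0)
  expect_identical(select_k(cc), 3L)
})

test_that("consensus labels agree with full-data k-means on the default cohort features", {
  coh <- small_cohort()
  feats <- zscore_cols(cbind(coh$true_fractions), warn = FALSE)
  cc <- consensus_cluster(feats, k_values = 3, reps = 50, seed = 1)
  km <- withr::with_seed(1, kmeans(feats, centers = 3, nstart = 25)$cluster)
  expect_gte(adjusted_rand_index(cc$labels[["3"]], km), 0.9)
})

test_that("consensus is exactly invariant to sample-order permutation", {
  b <- make_blobs(n_per = 10)
  cc1 <- consensus_cluster(b$x, k_values = 3, reps = 30, seed = 2)
  perm <- withr::with_seed(9, sample(nrow(b$x)))
  cc2 <- consensus_cluster(b$x[perm, ], k_values = 3, reps = 30, seed = 2)
  ids <- rownames(b$x)
  expect_lt(max(abs(cc1$consensus[["3"]][ids, ids] -
                    cc2$consensus[["3"]][ids, ids])), 1e-12)
  expect_identical(cc1$labels[["3"]][ids], cc2$labels[["3"]][ids])
})

test_that("consensus parameter validation", {
  b <- make_blobs(n_per = 5)
  expect_error(consensus_cluster(b$x, k_values = 3, reps = 5,
                                 subsample_fraction = 1.2), "subsample")
  expect_error(consensus_cluster(b$x, k_values = 30, reps = 5), "exceeds|samples")
})

test_that("PAC statistic and select_k follow their definitions", {
  # perfect block-binary consensus: PAC = 0
  cm <- kronecker(diag(2), matrix(1, 3, 3))
  expect_equal(pac_statistic(cm), 0)
  # half the off-diagonal entries ambiguous
  cm2 <- matrix(0.5, 4, 4); diag(cm2) <- 1
  expect_equal(pac_statistic(cm2), 1)
  # single-candidate selection warns
  b <- make_blobs(n_per = 8)
  cc <- consensus_cluster(b$x, k_values = 5, reps = 10, seed = 1)
  expect_warning(k <- select_k(cc), "single candidate")
  expect_identical(k, 5L)
})

test_that("cluster naming follows the CD8 / stromal argmax rules", {
  # synthetic standardized profile with transparent structure
  n <- 30
  feats <- matrix(0, n, 3,
                  dimnames = list(sprintf("S%02d", 1:n),
                                  c("T_cells_CD8", "Fibroblasts", "Neutrophils")))
  labels <- rep(1:3, each = 10)
  feats[labels == 1, "Fibroblasts"] <- 2    # IE-like
  feats[labels == 2, "Neutrophils"] <- 2    # IS-like
  feats[labels == 3, "T_cells_CD8"] <- 2    # IA-like
  feats <- feats + withr::with_seed(4, matrix(rnorm(n * 3, sd = 0.01), n, 3))
  prof <- structure(list(sample_ids = rownames(feats),
                         feature_ids = colnames(feats),
                         raw = feats, standardized = zscore_cols(feats)),
                    class = "cell_fraction_profile")
  naming <- name_clusters(setNames(labels, rownames(feats)), prof)
  expect_identical(unname(naming$cluster_map[c("1", "2", "3")]),
                   c("IE", "IS", "IA"))
  expect_identical(unname(naming$subtype[1]), "IE")
  expect_identical(sort(unique(naming$subtype)), c("IA", "IE", "IS"))
})

test_that("cluster naming recovers planted subtype identities", {
  coh <- small_cohort()
  sig <- small_signature()
  prof <- build_cell_feature_matrix(coh$expression, sig$signature,
                                    sig$fibroblast_markers)
  cc <- consensus_cluster(prof$standardized, k_values = 3, reps = 40, seed = 1)
  naming <- name_clusters(cc$labels[["3"]], prof)
  expect_gte(mean(naming$subtype == coh$true_labels), 0.95)
})

test_that("more repeats leave the partition essentially unchanged", {
  coh <- small_cohort()
  feats <- zscore_cols(coh$true_fractions, warn = FALSE)
  cc100 <- consensus_cluster(feats, k_values = 3, reps = 100, seed = 1)
  cc400 <- consensus_cluster(feats, k_values = 3, reps = 400, seed = 1)
  # align cluster indices via the confusion matrix before comparing
  expect_gte(adjusted_rand_index(cc100$labels[["3"]], cc400$labels[["3"]]),
             0.96)
})
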