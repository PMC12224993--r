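test_that("pairwise DEGs recover planted markers and reject nulls", {
  coh <- small_cohort()
  lg <- to_log2(coh$expression)
  degs <- pairwise_degs(lg, coh$true_labels)
  expect_true(all(degs$table$adjusted_p >= 0 & degs$table$adjusted_p <= 1))
  # one row per gene x ordered comparison
  expect_identical(nrow(degs$table), nrow(lg) * 6L)

  # markers of each subtype's elevated cell types land in that list only
  sig_types <- list(IE = "Fibroblasts", IS = "Neutrophils", IA = "T_cells_CD8")
  for (st in names(sig_types)) {
    planted <- names(coh$marker_map)[coh$marker_map == sig_types[[st]]]
    expect_gte(mean(planted %in% degs$up_lists[[st]]), 2 / 3)
    other <- setdiff(names(degs$up_lists), st)
    expect_false(any(planted %in% unlist(degs$up_lists[other])))
  }
  # filler genes have identical distributions across groups: none selected
  filler <- setdiff(rownames(lg), names(coh$marker_map))
  expect_lt(mean(filler %in% unlist(degs$up_lists)), 0.02)
})

test_that("pairwise DEGs are invariant to sample order and constant genes", {
  coh <- small_cohort()
  lg <- to_log2(coh$expression)
  sub <- expression_matrix(unclass(lg)[1:80, ], "log2")
  d1 <- pairwise_degs(sub, coh$true_labels)
  perm <- withr::with_seed(8, sample(ncol(sub)))
  d2 <- pairwise_degs(expression_matrix(unclass(sub)[, perm], "log2"),
                      coh$true_labels[perm])
  expect_identical(d1$up_lists, d2$up_lists)
  # adding an all-constant gene changes nothing for the others
  aug <- rbind(unclass(sub), ZCONST = rep(3, ncol(sub)))
  d3 <- pairwise_degs(expression_matrix(aug, "log2"), coh$true_labels)
  expect_identical(d1$up_lists, d3$up_lists)
  expect_false("ZCONST" %in% unlist(d3$up_lists))
})

test_that("pairwise DEGs validate inputs", {
  coh <- small_cohort()
  expect_error(pairwise_degs(coh$expression, coh$true_labels), "log2")
  lab <- coh$true_labels
  lab[lab == "IS"][-(1:2)] <- "IA"  # leaves IS with 2 samples
  expect_error(pairwise_degs(to_log2(coh$expression), lab), "fewer than 3")
})

test_that("remove_common removes genes shared by two or more lists and is idempotent", {
  lists <- list(IE = c("g1", "g2"), IS = "g2", IA = character())
  out <- remove_common(lists)
  expect_identical(out, list(IE = "g1", IS = character(), IA = character()))
  expect_identical(remove_common(out), out)
  # gene in all three lists vanishes everywhere
  out2 <- remove_common(list(IE = "g9", IS = c("g9", "g3"), IA = "g9"))
  expect_false("g9" %in% unlist(out2))
  # already-disjoint input unchanged
  disj <- list(IE = "a", IS = "b", IA = "c")
  expect_identical(remove_common(disj), disj)
})

test_that("random-forest reduction keeps informative genes and drops noise", {
  # 20 planted genes, each with an independent subtype-specific shift,
  # diluted with 20 label-independent noise genes
  n_per <- 30
  labels <- setNames(rep(c("IE", "IS", "IA"), each = n_per),
                     sprintf("S%03d", 1:(3 * n_per)))
  planted <- sprintf("PL%02d", 1:20)
  owner <- rep(c("IE", "IS", "IA"), length.out = 20)
  noise <- sprintf("NZ%02d", 1:20)
  m <- withr::with_seed(99, {
    mm <- matrix(rnorm(40 * 3 * n_per, mean = 6, sd = 1), 40, 3 * n_per,
                 dimnames = list(c(planted, noise), names(labels)))
    for (i in seq_along(planted)) {
      mm[planted[i], labels == owner[i]] <-
        mm[planted[i], labels == owner[i]] + 2
    }
    mm
  })
  expr <- expression_matrix(m, "log2")
  cand <- lapply(split(c(planted, noise),
                       rep(c("IE", "IS", "IA"), length.out = 40)), c)
  panel <- rf_reduce(expr, labels, cand, trees = 1000, seed = 5)
  kept <- panel_genes(panel)
  expect_true(all(kept %in% unlist(cand)))
  expect_gte(mean(planted %in% kept), 0.8)
  expect_lte(mean(noise %in% kept), 0.2)
  # subtype assignment preserved
  for (g in names(cand)) {
    expect_true(all(panel$genes_by_subtype[[g]] %in% cand[[g]]))
  }
  # determinism
  panel2 <- rf_reduce(expr, labels, cand, trees = 1000, seed = 5)
  expect_identical(panel$genes_by_subtype, panel2$genes_by_subtype)
})

test_that("full panel selection yields three non-empty disjoint lists across seeds", {
  coh <- small_cohort()
  lg <- to_log2(coh$expression)
  for (seed in c(1, 2)) {
    panel <- select_panel(lg, coh$true_labels, trees = 300, seed = seed)
    sizes <- lengths(panel$genes_by_subtype)
    expect_true(all(sizes > 0))
    expect_false(anyDuplicated(panel_genes(panel)) > 0)
  }
})

test_that("top_subtype_sets ranks and truncates per-subtype up-lists", {
  coh <- small_cohort()
  degs <- pairwise_degs(to_log2(coh$expression), coh$true_labels)
  sets <- top_subtype_sets(degs, n = 5)
  expect_true(all(lengths(sets$sets) <= 5))
  expect_true(all(names(sets$sets) %in% c("TME_IE", "TME_IS", "TME_IA")))
  for (nm in names(sets$sets)) {
    st <- sub("TME_", "", nm)
    expect_true(all(sets$sets[[nm]] %in% degs$up_lists[[st]]))
  }
})
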