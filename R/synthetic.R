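# Synthetic cohorts with planted three-subtype TME structure.
#
# Bulk samples are cell-type mixtures: expression = basis %*% fractions,
# perturbed by multiplicative lognormal noise. Per-sample fractions follow a
# subtype-specific Dirichlet; the three subtypes differ only through which
# cell types carry elevated concentration mass, mirroring the infiltration
# contrasts that define the IE / IS / IA phenotypes (stromal vs
# neutrophil/M0/mast vs CD8/M1/Tfh).

#' The 23 TME cell-feature labels
#'
#' The 22 leukocyte fraction features plus the fibroblast score feature used
#' throughout subtype discovery.
#'
#' @return Character vector of length 23.
#' @export
tme_cell_types <- function() {
  c("B_cells_naive", "B_cells_memory", "Plasma_cells", "T_cells_CD8",
    "T_cells_CD4_naive", "T_cells_CD4_memory_resting",
    "T_cells_CD4_memory_activated", "T_cells_follicular_helper",
    "T_cells_regulatory", "T_cells_gamma_delta", "NK_cells_resting",
    "NK_cells_activated", "Monocytes", "Macrophages_M0", "Macrophages_M1",
    "Macrophages_M2", "Dendritic_cells_resting", "Dendritic_cells_activated",
    "Mast_cells_resting", "Mast_cells_activated", "Eosinophils",
    "Neutrophils", "Fibroblasts")
}

# Cell types whose infiltration is elevated in each subtype (qualitative
# phenotype contrasts encoded quantitatively in the Dirichlet prior).
subtype_signature_types <- function() {
  list(
    IE = c("Fibroblasts", "Macrophages_M2", "Dendritic_cells_resting",
           "Eosinophils"),
    IS = c("Neutrophils", "Macrophages_M0", "Mast_cells_activated"),
    IA = c("T_cells_CD8", "Macrophages_M1", "T_cells_follicular_helper",
           "T_cells_CD4_memory_activated")
  )
}

#' Specify a synthetic TME cohort
#'
#' Defaults define the reference simulation conditions used across the test
#' suite: 100 samples per subtype, 23 cell types, 5 markers per type with a
#' 2^5.5-fold within-column elevation (canonical lineage markers are
#' enriched tens-to-hundreds-fold in their own cell type, and the elevation
#' must survive mixture dilution to remain detectable in bulk),
#' subtype-specific Dirichlet mixing with
#' total concentration mass 30 (elevated types carry 6x the baseline mass;
#' CD8 T cells in IS carry 0.2x), and lognormal expression noise with
#' sigma 0.5.
#'
#' @param n_genes total number of genes (markers plus unstructured filler).
#' @param markers_per_type marker genes planted per cell type.
#' @param marker_effect log2 elevation of a marker within its own cell type.
#' @param n_per_subtype samples per subtype.
#' @param noise_sd sigma of the elementwise lognormal expression noise.
#' @param dirichlet_mass total Dirichlet concentration per subtype.
#' @param boost concentration multiplier for a subtype's elevated cell types.
#' @param cd8_depletion concentration multiplier for CD8 T cells in IS.
#' @param seed base seed; substreams (basis / fractions / noise / cells) are
#'   derived as `seed + 1 .. seed + 4`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_genes = 500, markers_per_type = 5,
                        marker_effect = 5.5, n_per_subtype = 100,
                        noise_sd = 0.5, dirichlet_mass = 30, boost = 6,
                        cd8_depletion = 0.2, seed = 1) {
  types <- tme_cell_types()
  C <- length(types)
  if (markers_per_type * C > n_genes) {
    stop_("markers_per_type * n_cell_types (%d) exceeds n_genes (%d)",
          markers_per_type * C, n_genes)
  }
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  sig <- subtype_signature_types()
  conc <- sapply(c("IE", "IS", "IA"), function(st) {
    a <- stats::setNames(rep(1, C), types)
    a[sig[[st]]] <- boost
    if (st == "IS") a["T_cells_CD8"] <- cd8_depletion
    a / sum(a) * dirichlet_mass
  })
  if (any(conc <= 0)) stop_("Dirichlet concentrations must be positive")
  structure(list(n_genes = n_genes, cell_types = types,
                 markers_per_type = markers_per_type,
                 marker_effect = marker_effect,
                 n_per_subtype = n_per_subtype, noise_sd = noise_sd,
                 concentrations = conc, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate the cell-type basis (profile) matrix
#'
#' Baseline entries are lognormal (meanlog 1, sdlog 0.5); each cell type's
#' markers are multiplied by `2^marker_effect` in its own column only.
#'
#' @param spec a [cohort_spec()].
#' @return List with `basis` (genes x cell types) and `marker_map` (named
#'   character vector: gene -> owning cell type).
#' @export
simulate_basis <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  types <- spec$cell_types
  C <- length(types)
  m <- spec$markers_per_type
  marker_genes <- unlist(lapply(types, function(t) {
    sprintf("MK_%s_%d", toupper(t), seq_len(m))
  }))
  filler <- sprintf("G%04d", seq_len(spec$n_genes - length(marker_genes)))
  genes <- c(marker_genes, filler)
  with_seed_(spec$seed + 1L, {
    basis <- matrix(stats::rlnorm(length(genes) * C, meanlog = 1, sdlog = 0.5),
                    nrow = length(genes), ncol = C,
                    dimnames = list(genes, types))
    for (i in seq_along(types)) {
      idx <- (i - 1L) * m + seq_len(m)
      basis[idx, i] <- basis[idx, i] * 2^spec$marker_effect
    }
  })
  marker_map <- stats::setNames(rep(types, each = m), marker_genes)
  list(basis = basis, marker_map = marker_map)
}

#' Simulate a bulk cohort with planted subtypes
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort`: list with `expression` (linear-scale
#'   [expression_matrix()]), `true_labels`, `true_fractions` (samples x cell
#'   types, rows sum to 1), `basis`, `marker_map` and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  b <- simulate_basis(spec)
  types <- spec$cell_types
  C <- length(types)
  n <- spec$n_per_subtype
  labels <- rep(colnames(spec$concentrations), each = n)
  ids <- sprintf("S%03d", seq_along(labels))
  fractions <- with_seed_(spec$seed + 2L, {
    t(vapply(labels, function(st) {
      g <- stats::rgamma(C, shape = spec$concentrations[, st])
      g / sum(g)
    }, numeric(C)))
  })
  dimnames(fractions) <- list(ids, types)
  clean <- b$basis %*% t(fractions)
  noise <- with_seed_(spec$seed + 3L, {
    matrix(exp(stats::rnorm(length(clean), sd = spec$noise_sd)),
           nrow = nrow(clean))
  })
  expr <- expression_matrix(clean * noise, scale = "linear")
  structure(list(expression = expr,
                 true_labels = stats::setNames(labels, ids),
                 true_fractions = fractions, basis = b$basis,
                 marker_map = b$marker_map, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (%s)\n",
              nrow(x$expression), ncol(x$expression),
              paste(names(table(x$true_labels)), table(x$true_labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Derive a deconvolution signature from a synthetic cohort
#'
#' Restricts the basis to planted marker genes and the 22 leukocyte columns
#' (everything except the fibroblast feature), the layout expected by
#' [nusvr_deconvolve()]; fibroblast markers are returned separately for the
#' marker-mean score.
#'
#' @param cohort a `synthetic_cohort`.
#' @return List with `signature` (marker genes x 22) and
#'   `fibroblast_markers`.
#' @export
signature_from_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  fib <- "Fibroblasts"
  markers <- names(cohort$marker_map)
  sig_genes <- markers[cohort$marker_map != fib]
  list(signature = cohort$basis[sig_genes, setdiff(colnames(cohort$basis), fib),
                                drop = FALSE],
       fibroblast_markers = markers[cohort$marker_map == fib])
}

#' Simulate single-cell counts matched to a bulk cohort
#'
#' Each cell's type is drawn from its sample's true fraction vector; counts
#' are negative binomial with mean proportional to the type's basis profile
#' scaled to the cell's library size.
#'
#' @param cohort a `synthetic_cohort`.
#' @param cells_per_sample cells drawn per bulk sample.
#' @param lib_size_mean expected UMI count per cell.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param samples optional subset of sample ids to simulate.
#' @return List with `sc` (a [single_cell_counts()]) and `cell_types`
#'   (named vector, barcode -> true cell type).
#' @export
simulate_cells <- function(cohort, cells_per_sample = 500,
                           lib_size_mean = 5000, nb_dispersion = 0.5,
                           samples = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (cells_per_sample < 1) stop_("cells_per_sample must be >= 1")
  ids <- samples %||% rownames(cohort$true_fractions)
  types <- colnames(cohort$true_fractions)
  profiles <- sweep(cohort$basis, 2, colSums(cohort$basis), "/")
  size <- 1 / nb_dispersion
  with_seed_(cohort$spec$seed + 4L, {
    blocks <- vector("list", length(ids))
    cell_types_all <- vector("list", length(ids))
    for (si in seq_along(ids)) {
      s <- ids[si]
      ct <- sample(types, cells_per_sample, replace = TRUE,
                   prob = cohort$true_fractions[s, ])
      mu <- profiles[, ct, drop = FALSE] * lib_size_mean
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                    nrow = nrow(mu))
      dimnames(cnt) <- list(rownames(profiles),
                            sprintf("%s_C%04d", s, seq_len(cells_per_sample)))
      blocks[[si]] <- methods::as(cnt, "CsparseMatrix")
      cell_types_all[[si]] <- stats::setNames(ct, colnames(cnt))
    }
    counts <- do.call(cbind, blocks)
    cell_types <- do.call(c, cell_types_all)
    cell_sample <- stats::setNames(sub("_C\\d+$", "", colnames(counts)),
                                   colnames(counts))
    list(sc = single_cell_counts(counts, cell_sample),
         cell_types = cell_types)
  })
}
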