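# Accessors for the data files shipped with the package. Both reference
# objects are synthetic stand-ins constructed for this package (plausible
# marker symbols, simulated values); they demonstrate the expected layouts
# and are not measured reference profiles.

#' Packaged synthetic signature matrix and fibroblast markers
#'
#' A synthetic 22-cell-type signature matrix (66 marker genes, 3 per type)
#' in the genes x cell types layout expected by [nusvr_deconvolve()], plus
#' the fibroblast marker list for [marker_mean_score()]. Users analyzing
#' real cohorts should substitute a measured signature matrix.
#'
#' @return List with `signature` and `fibroblast_markers`.
#' @export
load_reference_signature <- function() {
  list(signature = read_signature_matrix(
         system.file("extdata", "signature_matrix_synthetic.tsv",
                     package = "tmesubtyper", mustWork = TRUE)),
       fibroblast_markers = readLines(
         system.file("extdata", "fibroblast_markers.txt",
                     package = "tmesubtyper", mustWork = TRUE)))
}

#' Packaged synthetic subtype panel (134 genes, 40/19/75)
#'
#' A synthetic stand-in reproducing the structure of the published
#' three-subtype feature-gene panel: 40 IE (stromal), 19 IS
#' (neutrophil/myeloid) and 75 IA (T-cell/interferon) genes, pairwise
#' disjoint. Useful for exercising classification plumbing at the published
#' panel's dimensions; it is not the published gene list.
#'
#' @return A [subtype_panel()].
#' @export
load_reference_panel <- function() {
  gsc <- read_gene_sets(system.file("extdata", "panel_134_synthetic.gmt",
                                    package = "tmesubtyper", mustWork = TRUE))
  subtype_panel(list(IE = gsc$sets$TME_IE, IS = gsc$sets$TME_IS,
                     IA = gsc$sets$TME_IA),
                provenance = list(source = "packaged synthetic stand-in"))
}
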