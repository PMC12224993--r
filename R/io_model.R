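# Model-bundle persistence: a directory with a JSON manifest (version,
# class labels, panel, hyperparameters, seed, payload checksums) plus one
# serialized payload per learner and one for the preprocessing state.
# Checksums are verified on load so that a tampered or truncated bundle is
# rejected; a reloaded bundle reproduces predictions bit-identically.

LEARNER_NAMES <- c("svm", "rf", "nnet", "xgboost", "dectree", "knn")

#' Save a trained ensemble to a bundle directory
#'
#' @param model a `tme_ensemble` from [train_ensemble()].
#' @param path bundle directory (created; existing manifest overwritten).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tme_ensemble"))
  missing <- setdiff(LEARNER_NAMES, names(model$learners))
  if (length(missing)) stop_("incomplete bundle: missing learner(s) %s",
                             paste(missing, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in LEARNER_NAMES) {
    f <- sprintf("learner_%s.rds", nm)
    saveRDS(model$learners[[nm]], file.path(path, f))
    files[nm] <- f
  }
  pre <- model[setdiff(names(model), "learners")]
  saveRDS(pre, file.path(path, "preprocessing.rds"))
  files["preprocessing"] <- "preprocessing.rds"
  checksums <- vapply(files, function(f) {
    unname(tools::md5sum(file.path(path, f)))
  }, character(1))
  manifest <- list(
    format = "tmesubtyper-bundle", format_version = 1L,
    package_version = model$version,
    class_order = model$class_order,
    panel = model$panel$genes_by_subtype,
    hyperparams = model$hyperparams,
    training_seed = model$training_seed,
    files = as.list(files), checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load an ensemble bundle
#'
#' Verifies the manifest checksums and the presence of all six learners.
#'
#' @param path bundle directory written by [save_model()].
#' @return A `tme_ensemble`.
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_("no manifest.json in %s", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  missing <- setdiff(c(LEARNER_NAMES, "preprocessing"), names(manifest$files))
  if (length(missing)) stop_("bundle manifest missing payload(s): %s",
                             paste(missing, collapse = ", "))
  for (nm in names(manifest$files)) {
    f <- file.path(path, manifest$files[[nm]])
    if (!file.exists(f)) stop_("bundle payload missing: %s", f)
    sum_now <- unname(tools::md5sum(f))
    if (!identical(sum_now, manifest$checksums[[nm]])) {
      stop_("checksum mismatch for %s: bundle is corrupted or tampered", f)
    }
  }
  pre <- readRDS(file.path(path, manifest$files[["preprocessing"]]))
  learners <- stats::setNames(lapply(LEARNER_NAMES, function(nm) {
    readRDS(file.path(path, manifest$files[[nm]]))
  }), LEARNER_NAMES)
  model <- c(pre, list(learners = learners))
  # restore canonical field order
  model <- model[c("panel", "gene_order", "feature_names", "feature_stats",
                   "learners", "class_order", "hyperparams", "training_seed",
                   "version")]
  class(model) <- "tme_ensemble"
  model
}
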