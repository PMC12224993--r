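# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a fixed RNG seed, restoring the previous RNG state
#' @noRd
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

#' Column-wise z-score with the constant-feature rule
#'
#' Columns with zero variance are mapped to all-zero (not NaN), with a
#' warning naming the offending features.
#' @noRd
zscore_cols <- function(x, warn = TRUE) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat) && warn) {
    warn_("constant feature(s) set to zero after standardization: %s",
          paste(colnames(x)[flat], collapse = ", "))
  }
  sdv[flat] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, flat] <- 0
  z
}

#' @noRd
assert_finite_matrix <- function(x, what = "matrix") {
  if (!all(is.finite(x))) stop_("%s contains non-finite values", what)
  invisible(x)
}
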