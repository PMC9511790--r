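#' @import Matrix
#' @importFrom data.table data.table fread fwrite setkey setkeyv := .N .SD as.data.table rbindlist setorder
#' @importFrom stats rnbinom rpois rbinom rmultinom rgamma rlnorm runif rnorm
#'   prcomp dist loess predict median quantile var sd cor p.adjust wilcox.test
#'   pnbinom setNames complete.cases aggregate
#' @importFrom utils read.table write.table
#' @importFrom methods as is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check that a numeric vector lies in a closed interval
#' @noRd
assert_in_range <- function(x, lo, hi, what) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi))
    abort("%s must lie in [%s, %s]", what, lo, hi)
  invisible(x)
}

#' Deterministic TSV writer (fixed float formatting, no scientific notation)
#'
#' All pipeline outputs go through this writer so that two runs with the same
#' configuration and seed produce byte-identical files.
#' @noRd
write_tsv_det <- function(df, path, digits = 10) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g", flag = "")
      df[[j]] <- trimws(df[[j]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Fix the sign of each column of a loading/eigenvector matrix
#'
#' The entry with the largest absolute value in each column is made positive,
#' so decompositions are deterministic up to this convention.
#' @noRd
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Squared Euclidean cross-distances between rows of two matrices
#' @noRd
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
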