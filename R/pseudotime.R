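#' Diffusion map of single-cell expression
#'
#' Builds a locally-scaled Gaussian kernel on Euclidean distances (each
#' cell's scale is its distance to the `kernel_scale`-th nearest neighbour),
#' applies density normalization so the embedding is robust to sampling
#' density, and returns the top right-eigenvectors of the resulting
#' transition matrix, excluding the trivial constant one. Component signs
#' are fixed as in [joint_pca()].
#'
#' @param x dense cells x genes matrix (log-normalized expression over
#'   highly variable genes).
#' @param n_components number of diffusion components to return.
#' @param kernel_scale neighbour index defining the local kernel scale.
#' @return list: `coords` (cells x n_components diffusion components, row
#'   names from `x`), `eigenvalues` (non-increasing).
#' @export
diffusion_map <- function(x, n_components = 2, kernel_scale = 5) {
  n <- nrow(x)
  if (n < kernel_scale + 1) abort("need more cells than kernel_scale")
  d2 <- cross_dist2(x, x)
  sig <- apply(d2, 1, function(r) sqrt(sort(r)[kernel_scale + 1L]))
  sig[sig == 0] <- min(sig[sig > 0], 1)
  K <- exp(-d2 / outer(sig, sig))
  diag(K) <- 0
  # connectivity check on the thresholded kernel graph
  reach <- logical(n); reach[1] <- TRUE; frontier <- 1L
  adj <- K > 1e-12
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reach))
    abort("kernel graph is disconnected; increase kernel_scale")
  q <- rowSums(K)
  K <- K / outer(q, q)                   # density normalization (alpha = 1)
  dr <- rowSums(K)
  S <- K / outer(sqrt(dr), sqrt(dr))     # symmetric conjugate of P
  ev <- eigen(S, symmetric = TRUE)
  idx <- 1L + seq_len(n_components)      # drop trivial first eigenvector
  psi <- ev$vectors[, idx, drop = FALSE] / sqrt(dr)
  psi <- fix_signs(psi)
  rownames(psi) <- rownames(x)
  list(coords = psi, eigenvalues = ev$values[idx])
}

#' Orient and scale a diffusion component into a pseudotime
#'
#' The first diffusion component is the trajectory axis; its sign is chosen
#' so that pseudotime correlates positively (Spearman) with the expression
#' of an anchor gene known to increase along the trajectory (e.g. an
#' embryonic haemoglobin for primitive erythropoiesis). Pseudotime is the
#' rank of the oriented component rescaled to exactly [0, 1].
#'
#' @param coords diffusion components (cells x components).
#' @param anchor_expr anchor-gene expression, aligned to rows of `coords`;
#'   must not be all zero.
#' @return object of class `PseudotimeOrdering`: data.frame with `cell_id`,
#'   `dc1`, `pseudotime`.
#' @export
orient_and_scale <- function(coords, anchor_expr) {
  if (all(anchor_expr == 0)) abort("anchor gene is unexpressed in all cells")
  dc1 <- coords[, 1]
  if (stats::cor(dc1, anchor_expr, method = "spearman") < 0) dc1 <- -dc1
  n <- length(dc1)
  pt <- (rank(dc1, ties.method = "average") - 1) / (n - 1)
  pt <- (pt - min(pt)) / (max(pt) - min(pt))   # exact [0, 1] despite ties
  res <- data.frame(cell_id = rownames(coords) %||% seq_len(n),
                    dc1 = dc1, pseudotime = pt,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("PseudotimeOrdering", class(res))
  res
}

#' LOESS curve of a quantity along pseudotime
#'
#' Local linear regression with tricube weights over the `span` fraction of
#' nearest points, evaluated on a fixed grid (local polynomial smoothing as
#' implemented in `stats::loess` with `degree = 1`, exact "direct" surface).
#'
#' @param x predictor (pseudotime in [0, 1]).
#' @param y response values aligned to `x`.
#' @param span fraction of points in each local neighbourhood.
#' @param grid evaluation grid; default 100 points spanning [0, 1]
#'   (restricted to the observed range to avoid extrapolation).
#' @return object of class `SmoothCurve`: data.frame with `grid` and
#'   `fitted`.
#' @export
loess_curve <- function(x, y, span = 0.5, grid = NULL) {
  n <- length(x)
  if (span * n < 3) abort("span * n must be at least 3")
  grid <- grid %||% seq(max(0, min(x)), min(1, max(x)), length.out = 100)
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be increasing")
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                      surface = "direct")
  out <- data.frame(grid = grid,
                    fitted = as.numeric(stats::predict(fit,
                                                       newdata = data.frame(x = grid))))
  if (any(!is.finite(out$fitted))) abort("LOESS fit produced non-finite values")
  class(out) <- c("SmoothCurve", class(out))
  out
}
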