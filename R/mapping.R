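#' Parameters for reference-atlas mapping and label transfer
#'
#' `k_neighbors = 30` is the study's voting neighbourhood; the remaining
#' values (number of highly variable genes and principal components, the
#' mutual-nearest-neighbour pairing depth and kernel bandwidth) are
#' configuration defaults.
#'
#' @param n_hvgs number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbours used for majority voting.
#' @param mnn_k neighbours searched per cell when pairing mutual nearest
#'   neighbours across batches.
#' @param mnn_sigma Gaussian kernel bandwidth for smoothing correction
#'   vectors, in cosine-normalized PCA units.
#' @param seed integer seed (mapping itself is deterministic; the seed is
#'   recorded for provenance).
#' @return an object of class `MappingParams`.
#' @export
mapping_params <- function(n_hvgs = 2000, n_pcs = 50, k_neighbors = 30,
                           mnn_k = 20, mnn_sigma = 0.1, seed = 1L) {
  if (k_neighbors < 1) abort("k_neighbors must be >= 1")
  if (n_pcs > n_hvgs) abort("n_pcs must not exceed n_hvgs")
  structure(list(n_hvgs = n_hvgs, n_pcs = n_pcs, k_neighbors = k_neighbors,
                 mnn_k = mnn_k, mnn_sigma = mnn_sigma, seed = as.integer(seed)),
            class = "MappingParams")
}

#' Select highly variable genes
#'
#' Genes are ranked by the variance of their log1p-normalized expression in
#' excess of a mean-variance trend (a local polynomial fit of per-gene
#' variance on per-gene mean); the top `n_hvgs` are returned.
#' Constant-expression genes rank last and are never selected when
#' `n_hvgs < n_genes`.
#'
#' @param logexpr dense cells x genes matrix of log1p-normalized expression
#'   (see [normalized_matrix()]).
#' @param n_hvgs number of genes to return; if it is at least the number of
#'   genes, all genes are returned with a warning.
#' @return character vector of gene identifiers, highest excess variance
#'   first.
#' @export
select_hvgs <- function(logexpr, n_hvgs = 2000) {
  mu <- colMeans(logexpr)
  v <- apply(logexpr, 2, stats::var)
  if (n_hvgs >= ncol(logexpr)) {
    if (n_hvgs > ncol(logexpr))
      warn("n_hvgs (%d) exceeds gene count (%d); returning all genes",
           n_hvgs, ncol(logexpr))
    return(colnames(logexpr))
  }
  fit <- tryCatch(
    stats::fitted(stats::loess(v ~ mu, span = 0.3, degree = 2,
                               family = "symmetric")),
    error = function(e) rep(mean(v), length(v)))
  resid <- v - fit
  resid[v == 0] <- -Inf
  colnames(logexpr)[order(resid, decreasing = TRUE)[seq_len(n_hvgs)]]
}

#' Joint PCA of reference and query expression
#'
#' The two log-normalized matrices are restricted to the highly variable
#' genes, row-stacked, cosine-normalized per cell (stabilizing the scale the
#' mutual-nearest-neighbour kernel operates on), column-centered and
#' decomposed. Component signs are fixed by making the largest-magnitude
#' loading of each component positive, so results are fully deterministic.
#'
#' @param ref_log,query_log dense cells x genes log-normalized matrices with
#'   cell row names; gene columns must include `hvgs`.
#' @param hvgs character vector of genes to use.
#' @param n_pcs number of components; reduced with a warning if it exceeds
#'   what the data support.
#' @return list: `coords` (all cells x n_pcs, reference rows first),
#'   `batch` (factor `"reference"`/`"query"`), `rotation`,
#'   `var_explained`.
#' @export
joint_pca <- function(ref_log, query_log, hvgs, n_pcs = 50) {
  x <- rbind(ref_log[, hvgs, drop = FALSE], query_log[, hvgs, drop = FALSE])
  nrm <- sqrt(rowSums(x^2)); nrm[nrm == 0] <- 1
  x <- x / nrm
  x <- sweep(x, 2, colMeans(x))
  max_pcs <- min(dim(x)) - 1L
  if (n_pcs > max_pcs) {
    warn("reducing n_pcs from %d to %d (limited by data)", n_pcs, max_pcs)
    n_pcs <- max_pcs
  }
  ev <- eigen(crossprod(x), symmetric = TRUE)
  rot <- fix_signs(ev$vectors[, seq_len(n_pcs), drop = FALSE])
  rownames(rot) <- hvgs
  coords <- x %*% rot
  rownames(coords) <- c(rownames(ref_log), rownames(query_log))
  list(coords = coords,
       batch = factor(rep(c("reference", "query"),
                          c(nrow(ref_log), nrow(query_log))),
                      levels = c("reference", "query")),
       rotation = rot,
       var_explained = pmax(ev$values[seq_len(n_pcs)], 0) /
         max(sum(pmax(ev$values, 0)), .Machine$double.eps))
}

# k smallest indices per row of a distance^2 matrix (ties by index)
knn_idx <- function(d2, k) {
  res <- apply(d2, 1, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Mutual-nearest-neighbour batch correction
#'
#' Mutual nearest pairs are found between the two batches in PCA space; each
#' query cell is then shifted by a Gaussian-kernel-weighted average of the
#' pair difference vectors (reference minus query), with kernel weights
#' based on the query cell's distance to each pair's query member. Reference
#' coordinates are returned unchanged.
#'
#' @param coords cells x dims matrix (as from [joint_pca()]).
#' @param batch factor with levels `reference`, `query`, aligned to rows.
#' @param mnn_k neighbour depth for pairing.
#' @param mnn_sigma kernel bandwidth.
#' @return list: `coords` (corrected), `pairs` (data.frame of reference and
#'   query row names of each mutual pair).
#' @export
mnn_correct <- function(coords, batch, mnn_k = 20, mnn_sigma = 0.1) {
  ref <- coords[batch == "reference", , drop = FALSE]
  qry <- coords[batch == "query", , drop = FALSE]
  k1 <- min(mnn_k, nrow(ref)); k2 <- min(mnn_k, nrow(qry))
  d2 <- cross_dist2(qry, ref)                      # query x reference
  nn_qr <- knn_idx(d2, k1)                         # per query: ref neighbours
  nn_rq <- knn_idx(t(d2), k2)                      # per ref: query neighbours
  hits_rq <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(ref)), k2), j = as.vector(nn_rq),
    x = TRUE, dims = c(nrow(ref), nrow(qry)))
  pair_q <- rep(seq_len(nrow(qry)), k1)
  pair_r <- as.vector(nn_qr)
  mutual <- hits_rq[cbind(pair_r, pair_q)]
  pair_q <- pair_q[mutual]; pair_r <- pair_r[mutual]
  if (!length(pair_q))
    abort("no mutual nearest pairs found; try a larger mnn_k")
  delta <- ref[pair_r, , drop = FALSE] - qry[pair_q, , drop = FALSE]
  # kernel anchored at pair midpoints: the two members of a symmetric pair
  # duo (r_j, q_i) / (r_i, q_j) share a midpoint, so their antisymmetric
  # within-batch components cancel and only the batch shift survives
  mid <- (ref[pair_r, , drop = FALSE] + qry[pair_q, , drop = FALSE]) / 2
  dq2 <- cross_dist2(qry, mid)                          # query x pairs
  dq2 <- sweep(dq2, 1, apply(dq2, 1, min))              # scale-free weights
  w <- exp(-dq2 / (2 * mnn_sigma^2))
  sw <- rowSums(w)
  deg <- sw < .Machine$double.eps * ncol(w)
  if (any(deg)) {              # kernel underflow: fall back to nearest pair
    nearest <- apply(dq2[deg, , drop = FALSE], 1, which.min)
    w[deg, ] <- 0
    w[cbind(which(deg), nearest)] <- 1
    sw <- rowSums(w)
  }
  correction <- (w %*% delta) / sw
  out <- coords
  out[batch == "query", ] <- qry + correction
  list(coords = out,
       pairs = data.frame(reference = rownames(ref)[pair_r],
                          query = rownames(qry)[pair_q],
                          stringsAsFactors = FALSE))
}

#' Transfer cell-type labels by joint-kNN majority voting
#'
#' For each query cell the `k_neighbors` nearest reference cells (Euclidean
#' distance in corrected PCA space) are tallied by cell type and the label is
#' the mode of the resulting Dirichlet posterior over type frequencies —
#' which reduces to the argmax of the counts, i.e. majority voting. Ties are
#' broken toward the type whose tied neighbours are nearer in summed
#' distance, then lexicographically. Confidence is the winning count over k.
#'
#' @param coords corrected coordinates (reference and query rows).
#' @param batch factor with levels `reference`, `query`.
#' @param ref_labels cell types of the reference cells, aligned to the
#'   reference rows of `coords`.
#' @param k_neighbors voting neighbourhood size.
#' @return object of class `MappingResult`: list with `assignment`
#'   (data.frame: cell_id, cell_type, confidence), `neighbors` (query x k
#'   matrix of reference cell ids) and `k`.
#' @export
transfer_labels <- function(coords, batch, ref_labels, k_neighbors = 30) {
  ref <- coords[batch == "reference", , drop = FALSE]
  qry <- coords[batch == "query", , drop = FALSE]
  if (k_neighbors > nrow(ref))
    abort("k_neighbors (%d) exceeds the number of reference cells (%d)",
          k_neighbors, nrow(ref))
  ref_labels <- as.character(ref_labels)
  d2 <- cross_dist2(qry, ref)
  nn <- knn_idx(d2, k_neighbors)
  assigned <- character(nrow(qry)); conf <- numeric(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    idx <- nn[i, ]
    types <- ref_labels[idx]
    counts <- table(types)
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) {
      sums <- vapply(top, function(tp)
        sum(sqrt(d2[i, idx[types == tp]])), 0)
      top <- top[order(sums, top)][1]
    }
    assigned[i] <- top
    conf[i] <- max(counts) / k_neighbors
  }
  neighbors <- matrix(rownames(ref)[t(nn)], nrow = nrow(qry), byrow = TRUE,
                      dimnames = list(rownames(qry), NULL))
  structure(list(assignment = data.frame(cell_id = rownames(qry),
                                         cell_type = assigned,
                                         confidence = conf,
                                         stringsAsFactors = FALSE),
                 neighbors = neighbors, k = k_neighbors),
            class = "MappingResult")
}

#' Flag reference cells that are neighbours of query cells
#'
#' Used to highlight, on a pre-computed reference 2-D embedding, the atlas
#' cells nearest to each query group (e.g. wildtype vs mutant embryos).
#' Flags for different groups are computed independently.
#'
#' @param result a `MappingResult`.
#' @param ref_cell_ids all reference cell ids (the embedding's rows).
#' @param query_groups optional named list of query cell-id vectors; default
#'   is a single group of all query cells.
#' @return data.frame: cell_id plus one logical column per group.
#' @export
highlight_neighbors <- function(result, ref_cell_ids, query_groups = NULL) {
  query_groups <- query_groups %||%
    list(all = result$assignment$cell_id)
  out <- data.frame(cell_id = ref_cell_ids, stringsAsFactors = FALSE)
  for (g in names(query_groups)) {
    hit <- unique(as.vector(
      result$neighbors[rownames(result$neighbors) %in% query_groups[[g]], ,
                       drop = FALSE]))
    out[[g]] <- ref_cell_ids %in% hit
  }
  out
}

#' Map query cells to a reference atlas end to end
#'
#' Convenience wrapper chaining normalization, HVG selection on the
#' concatenated data, joint PCA, MNN correction and label transfer.
#'
#' @param ref_cm,query_cm `CountMatrix` objects (QC-passed cells).
#' @param ref_labels reference cell types aligned to `cell_ids(ref_cm)`.
#' @param params a [mapping_params()].
#' @param correct apply MNN correction (default `TRUE`).
#' @return a `MappingResult` (see [transfer_labels()]) with the corrected
#'   coordinates attached as `$coords` and `$batch`.
#' @export
map_to_reference <- function(ref_cm, query_cm, ref_labels,
                             params = mapping_params(), correct = TRUE) {
  shared <- intersect(gene_ids(ref_cm), gene_ids(query_cm))
  ref_log <- normalized_matrix(subset_cells(ref_cm, genes = shared))
  qry_log <- normalized_matrix(subset_cells(query_cm, genes = shared))
  hvgs <- select_hvgs(rbind(ref_log, qry_log), params$n_hvgs)
  pca <- joint_pca(ref_log, qry_log, hvgs, params$n_pcs)
  coords <- if (correct)
    mnn_correct(pca$coords, pca$batch, params$mnn_k, params$mnn_sigma)$coords
  else pca$coords
  res <- transfer_labels(coords, pca$batch, ref_labels, params$k_neighbors)
  res$coords <- coords
  res$batch <- pca$batch
  res
}
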