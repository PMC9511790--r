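#' Per-embryo cell-type proportion table
#'
#' Proportions are computed over a shared cell-type vocabulary with an
#' additive pseudocount (default 1 cell per type), which keeps downstream
#' log2 ratios finite for cell types absent from an embryo.
#'
#' @param ann annotation data.frame with `cell_id`, `embryo_id`, `cell_type`
#'   and (optionally) `genotype` columns; embryos with zero cells are dropped
#'   with a warning if listed in `embryo_ids`.
#' @param pseudocount cells added to every (embryo, type) count.
#' @param cell_types vocabulary; defaults to the types present.
#' @param embryo_ids embryos to tabulate; defaults to those present.
#' @return list of class `ProportionTable`: `proportions` (embryos x types,
#'   rows sum to 1), `counts` (raw), `embryo_info` (embryo_id, genotype,
#'   optional `host_embryo_id`).
#' @export
proportions <- function(ann, pseudocount = 1, cell_types = NULL,
                        embryo_ids = NULL) {
  cell_types <- cell_types %||% sort(unique(ann$cell_type))
  embryo_ids <- embryo_ids %||% unique(ann$embryo_id)
  empty <- setdiff(embryo_ids, unique(ann$embryo_id))
  if (length(empty)) {
    warn("dropping embryo(s) with zero cells: %s", paste(empty, collapse = ", "))
    embryo_ids <- setdiff(embryo_ids, empty)
  }
  counts <- table(factor(ann$embryo_id, levels = embryo_ids),
                  factor(ann$cell_type, levels = cell_types))
  counts <- matrix(as.numeric(counts), nrow = length(embryo_ids),
                   dimnames = list(embryo_ids, cell_types))
  padded <- counts + pseudocount
  props <- padded / rowSums(padded)
  info_cols <- intersect(c("genotype", "host_embryo_id"), names(ann))
  info <- unique(ann[, c("embryo_id", info_cols), drop = FALSE])
  info <- info[match(embryo_ids, info$embryo_id), , drop = FALSE]
  rownames(info) <- NULL
  structure(list(proportions = props, counts = counts, embryo_info = info),
            class = "ProportionTable")
}

#' Log2 composition shift of each embryo against a baseline
#'
#' `mode = "ko_vs_wt_mean"`: each non-WT embryo is compared with the
#' arithmetic mean of the WT embryos' proportion vectors. `mode =
#' "chimaera_host_matched"`: each embryo is compared with its matched host
#' embryo's proportions (requires a `host_embryo_id` column in the
#' annotation used to build the table). Pseudocounts were already applied by
#' [proportions()], so ratios are finite.
#'
#' @param tab a `ProportionTable`.
#' @param mode comparison baseline (see above).
#' @return data.frame: embryo_id, cell_type, log2_ratio (long format).
#' @export
log2_shift <- function(tab, mode = c("ko_vs_wt_mean", "chimaera_host_matched")) {
  mode <- match.arg(mode)
  p <- tab$proportions
  info <- tab$embryo_info
  if (mode == "ko_vs_wt_mean") {
    if (is.null(info$genotype)) abort("genotype column required")
    wt <- info$embryo_id[info$genotype == "WT"]
    if (!length(wt)) abort("no WT embryos to form the baseline")
    baseline <- colMeans(p[wt, , drop = FALSE])
    query <- setdiff(rownames(p), wt)
    ratios <- sweep(log2(p[query, , drop = FALSE]), 2, log2(baseline))
  } else {
    if (is.null(info$host_embryo_id))
      abort("chimaera mode requires a host_embryo_id column")
    query <- info$embryo_id[!is.na(info$host_embryo_id)]
    if (!length(query))
      abort("chimaera mode requires at least one embryo with a host link")
    host <- info$host_embryo_id[match(query, info$embryo_id)]
    missing_host <- setdiff(host, rownames(p))
    if (length(missing_host))
      abort("host embryo(s) missing from table: %s",
            paste(missing_host, collapse = ", "))
    ratios <- log2(p[query, , drop = FALSE]) - log2(p[host, , drop = FALSE])
    rownames(ratios) <- query
  }
  data.frame(embryo_id = rep(rownames(ratios), ncol(ratios)),
             cell_type = rep(colnames(ratios), each = nrow(ratios)),
             log2_ratio = as.vector(ratios),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage query embryos against staged reference embryos
#'
#' PCA is fitted on the row-stacked proportion matrix of query plus
#' reference embryos (rows centered, not scaled). For each query embryo the
#' Euclidean distance to every reference embryo is measured in PC space; a
#' stage's raw score is the mean inverse distance over that stage's
#' reference embryos, and scores are minmax-normalized across stages to
#' [0, 1] (all-equal scores map to 1). A zero distance (identical
#' composition) promotes that stage's score to the maximum before
#' normalization.
#'
#' @param query_props query embryos x types proportion matrix (or a
#'   `ProportionTable`).
#' @param ref_props reference embryos x types proportion matrix (or a
#'   `ProportionTable`), over the same cell-type columns.
#' @param ref_stages stage label per reference embryo.
#' @param n_pcs PCs retained; default is the number of stages minus 1.
#' @return object of class `StageAssignment`: list with `scores` (query x
#'   stage matrix in [0, 1]), `stage` (named argmax per query; ties broken
#'   toward the earlier stage), `distances` (query x reference embryos).
#' @export
stage_embryos <- function(query_props, ref_props, ref_stages, n_pcs = NULL) {
  if (inherits(query_props, "ProportionTable"))
    query_props <- query_props$proportions
  if (inherits(ref_props, "ProportionTable"))
    ref_props <- ref_props$proportions
  if (!identical(colnames(query_props), colnames(ref_props))) {
    shared <- intersect(colnames(query_props), colnames(ref_props))
    if (length(shared) < 2) abort("proportion tables share too few cell types")
    query_props <- query_props[, shared, drop = FALSE]
    ref_props <- ref_props[, shared, drop = FALSE]
  }
  stages <- unique(ref_stages)          # keep given stage order
  n_pcs <- n_pcs %||% max(1L, length(stages) - 1L)
  x <- rbind(query_props, ref_props)
  x <- sweep(x, 2, colMeans(x))
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  ev <- eigen(crossprod(x), symmetric = TRUE)
  rot <- fix_signs(ev$vectors[, seq_len(n_pcs), drop = FALSE])
  pc <- x %*% rot
  nq <- nrow(query_props)
  qpc <- pc[seq_len(nq), , drop = FALSE]
  rpc <- pc[-seq_len(nq), , drop = FALSE]
  d <- sqrt(cross_dist2(qpc, rpc))
  rownames(d) <- rownames(query_props); colnames(d) <- rownames(ref_props)
  raw <- matrix(NA_real_, nq, length(stages),
                dimnames = list(rownames(query_props), stages))
  for (s in stages) {
    cols <- which(ref_stages == s)
    inv <- 1 / d[, cols, drop = FALSE]
    raw[, s] <- rowMeans(inv)
  }
  # identical composition (zero distance): promote that stage to the row max
  for (i in seq_len(nq)) {
    inf_s <- which(!is.finite(raw[i, ]))
    if (length(inf_s)) {
      mx <- if (length(inf_s) < ncol(raw))
        max(raw[i, -inf_s]) else 0
      raw[i, inf_s] <- mx + 1
    }
  }
  scores <- t(apply(raw, 1, function(r) {
    rng <- range(r)
    if (diff(rng) == 0) rep(1, length(r)) else (r - rng[1]) / diff(rng)
  }))
  dimnames(scores) <- dimnames(raw)
  stage <- apply(scores, 1, function(r) stages[which.max(r)])
  structure(list(scores = scores, stage = stage, distances = d,
                 stages = stages),
            class = "StageAssignment")
}
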