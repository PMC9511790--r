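#' Differential-expression and marker-rule parameters
#'
#' Significance requires a Benjamini-Hochberg adjusted p-value of at most
#' `fdr` (default 1%) AND an absolute log2 fold change of at least
#' `min_abs_log2fc` (default 1). Pseudobulk samples with fewer than
#' `min_cells_per_sample` member cells are dropped, and each group must
#' retain at least `min_samples_per_group` samples.
#'
#' @param fdr BH false-discovery-rate threshold.
#' @param min_abs_log2fc minimum absolute log2 fold change.
#' @param min_cells_per_sample minimum cells backing a pseudobulk sample.
#' @param min_samples_per_group minimum replicates per group.
#' @return an object of class `DEParams`.
#' @export
de_params <- function(fdr = 0.01, min_abs_log2fc = 1,
                      min_cells_per_sample = 10, min_samples_per_group = 2) {
  if (fdr <= 0 || fdr >= 1) abort("fdr must be in (0, 1)")
  if (min_abs_log2fc < 0) abort("min_abs_log2fc must be >= 0")
  structure(list(fdr = fdr, min_abs_log2fc = min_abs_log2fc,
                 min_cells_per_sample = min_cells_per_sample,
                 min_samples_per_group = min_samples_per_group),
            class = "DEParams")
}

#' @rdname de_params
#' @param pairwise_fraction a gene is a cell-type marker iff it is DE
#'   (upregulated in that type) in strictly more than this fraction of the
#'   pairwise comparisons against the other types.
#' @export
marker_params <- function(pairwise_fraction = 0.75) {
  if (pairwise_fraction <= 0 || pairwise_fraction > 1)
    abort("pairwise_fraction must be in (0, 1]")
  structure(list(pairwise_fraction = pairwise_fraction),
            class = "MarkerParams")
}

#' Build a pseudobulk matrix for one cell type
#'
#' Counts are summed per sample (embryo by default) over that sample's cells
#' of the given type; samples backed by too few cells are dropped.
#' Normalization factors are DESeq2's median-of-ratios estimator: per
#' sample, the median over genes (restricted to genes with an all-sample
#' nonzero geometric mean) of count / geometric mean.
#'
#' @param cm a `CountMatrix`; @param ann annotation with `cell_id`,
#'   `cell_type`, `genotype` and the `group_by` column.
#' @param cell_type the cell type to aggregate (`NULL` = all cells).
#' @param group_by annotation column defining samples (default `embryo_id`).
#' @param min_cells_per_sample dropped-sample threshold.
#' @return object of class `PseudobulkMatrix`: `counts` (genes x samples
#'   integer matrix), `factor` (named, > 0), `group` (genotype per sample),
#'   `n_cells` (cells per sample).
#' @export
make_pseudobulk <- function(cm, ann, cell_type = NULL, group_by = "embryo_id",
                            min_cells_per_sample = 10) {
  ann <- ann[match(cell_ids(cm), ann$cell_id), , drop = FALSE]
  keep <- if (is.null(cell_type)) rep(TRUE, nrow(ann)) else
    ann$cell_type == cell_type
  if (!any(keep)) abort("no cells of type '%s'", cell_type)
  sample_of <- ann[[group_by]][keep]
  m <- cm$counts[keep, , drop = FALSE]
  samples <- unique(sample_of)
  agg <- t(vapply(samples, function(s)
    Matrix::colSums(m[sample_of == s, , drop = FALSE]),
    numeric(ncol(m))))
  counts <- t(agg)                      # genes x samples
  colnames(counts) <- samples
  n_cells <- as.vector(table(factor(sample_of, levels = samples)))
  ok <- n_cells >= min_cells_per_sample
  counts <- counts[, ok, drop = FALSE]
  samples <- samples[ok]; n_cells <- n_cells[ok]
  if (!length(samples)) abort("no sample meets min_cells_per_sample")
  sf <- median_of_ratios(counts)
  grp <- ann$genotype[keep][match(samples, sample_of)]
  structure(list(counts = counts,
                 factor = stats::setNames(sf, samples),
                 group = stats::setNames(grp, samples),
                 n_cells = stats::setNames(n_cells, samples)),
            class = "PseudobulkMatrix")
}

#' Median-of-ratios normalization factors
#'
#' @param counts genes x samples matrix.
#' @return positive factor per sample (all-1 fallback when no gene is
#'   expressed in every sample).
#' @export
median_of_ratios <- function(counts) {
  loggeo <- rowMeans(log(counts))
  apply(counts, 2, function(cnts) {
    ok <- is.finite(loggeo) & cnts > 0
    if (!any(ok)) return(1)
    exp(stats::median(log(cnts[ok]) - loggeo[ok]))
  })
}

#' Pseudobulk negative-binomial differential expression
#'
#' Fits, per gene, a negative-binomial generalized linear model with log
#' link and an offset formed from the sample's median-of-ratios factor and
#' library size; tagwise dispersions are shrunk toward a mean-dispersion
#' trend by empirical Bayes, and the group coefficient is tested with the
#' quasi-likelihood F-test (`method = "ql"`, via edgeR, the standard
#' machinery for this model family) or a likelihood-ratio test (`method =
#' "lrt"`). Genes with all-zero counts are excluded from testing and from
#' the BH family. Log2 fold changes are reported from the normalized group
#' means moderated by a gene-relative prior (1% of the gene's mean
#' normalized count), which keeps estimates finite when a gene is observed
#' in only one group while leaving fold changes exactly invariant to
#' rescaling counts and normalization factors together.
#'
#' @param pb a `PseudobulkMatrix` with exactly two groups.
#' @param params a [de_params()].
#' @param method `"ql"` or `"lrt"`.
#' @param contrast optional 2-vector `c(baseline, treatment)`; log2 fold
#'   changes are treatment over baseline. Default: first group level is the
#'   baseline.
#' @param genes optional restriction of the tested (and BH) family, e.g. to
#'   a marker-gene list.
#' @return data.frame of class `DEResult`: gene, log2fc, dispersion, stat,
#'   pvalue, padj, significant, direction (+1/-1/0).
#' @export
nb_test <- function(pb, params = de_params(), method = c("ql", "lrt"),
                    contrast = NULL, genes = NULL) {
  method <- match.arg(method)
  grp <- pb$group
  lev <- contrast %||% unique(grp)
  if (length(unique(grp)) != 2 || !setequal(lev, unique(grp)))
    abort("nb_test requires exactly two groups")
  if (any(table(grp) < params$min_samples_per_group))
    abort("each group needs at least %d samples", params$min_samples_per_group)
  counts <- pb$counts
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing)) warn("%d restriction gene(s) absent from matrix",
                              length(missing))
    counts <- counts[intersect(genes, rownames(counts)), , drop = FALSE]
  }
  nonzero <- rowSums(counts) > 0
  counts <- counts[nonzero, , drop = FALSE]
  group <- factor(grp, levels = lev)
  lib <- colSums(counts)
  nf <- pb$factor / lib
  nf <- nf / exp(mean(log(nf)))
  y <- edgeR::DGEList(counts = counts, group = group,
                      norm.factors = as.numeric(nf))
  design <- stats::model.matrix(~group)
  y <- edgeR::estimateDisp(y, design)
  if (method == "ql") {
    fit <- edgeR::glmQLFit(y, design)
    tst <- edgeR::glmQLFTest(fit, coef = 2)
  } else {
    fit <- edgeR::glmFit(y, design)
    tst <- edgeR::glmLRT(fit, coef = 2)
  }
  tab <- tst$table
  # fold change from normalized group means with a gene-relative prior (1%
  # of the gene's mean normalized count): finite for one-group-only genes
  # (capped at log2(201) ~ 7.65) and exactly invariant to rescaling counts
  # and factors together, which a fixed pseudocount cannot be
  eff <- lib * nf
  eff <- eff / exp(mean(log(eff)))
  norm <- sweep(counts, 2, eff, "/")
  m1 <- rowMeans(norm[, group == lev[1], drop = FALSE])
  m2 <- rowMeans(norm[, group == lev[2], drop = FALSE])
  prior <- 0.005 * (m1 + m2)
  lfc <- log2((m2 + prior) / (m1 + prior))
  padj <- stats::p.adjust(tab$PValue, method = "BH")
  sig <- padj <= params$fdr & abs(lfc) >= params$min_abs_log2fc
  res <- data.frame(gene = rownames(tab),
                    log2fc = lfc,
                    dispersion = y$tagwise.dispersion,
                    stat = tab[[grep("^(F|LR)$", names(tab), value = TRUE)[1]]],
                    pvalue = tab$PValue,
                    padj = padj,
                    significant = sig,
                    direction = ifelse(sig, sign(lfc), 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("DEResult", class(res))
  res
}

#' Identify cell-type marker genes by the pairwise-DE rule
#'
#' For each cell type, differential expression is run against every other
#' type (pseudobulk per embryo within each type); a gene is a marker of a
#' type iff it is significantly upregulated in that type in strictly more
#' than `pairwise_fraction` of its C - 1 comparisons.
#'
#' @param cm reference `CountMatrix`; @param ann reference annotation
#'   (`cell_type`, `embryo_id` used as replicates).
#' @param params a [de_params()]; @param mparams a [marker_params()].
#' @param method test flavour passed to [nb_test()].
#' @return named list (one per cell type) of marker gene-id vectors; the
#'   per-type DE hit counts are attached as attribute `n_de`.
#' @export
find_markers <- function(cm, ann, params = de_params(),
                         mparams = marker_params(), method = "ql") {
  types <- sort(unique(ann$cell_type))
  C <- length(types)
  if (C < 3) abort("marker rule needs at least 3 cell types (got %d)", C)
  pbs <- lapply(types, function(tp) {
    pb <- make_pseudobulk(cm, ann, cell_type = tp,
                          min_cells_per_sample = params$min_cells_per_sample)
    colnames(pb$counts) <- paste(tp, colnames(pb$counts), sep = ":")
    names(pb$factor) <- names(pb$group) <- colnames(pb$counts)
    pb$group[] <- tp
    pb
  })
  names(pbs) <- types
  up <- matrix(0L, ncol(cm$counts), C, dimnames = list(gene_ids(cm), types))
  for (a in seq_len(C - 1)) for (b in (a + 1):C) {
    cmb <- cbind(pbs[[a]]$counts, pbs[[b]]$counts)
    pb <- structure(list(
      counts = cmb,
      factor = median_of_ratios(cmb),   # rescale on the joint matrix
      group = c(pbs[[a]]$group, pbs[[b]]$group),
      n_cells = c(pbs[[a]]$n_cells, pbs[[b]]$n_cells)),
      class = "PseudobulkMatrix")
    res <- nb_test(pb, params, method = method,
                   contrast = c(types[b], types[a]))  # log2fc: a over b
    hit_a <- res$gene[res$significant & res$log2fc > 0]
    hit_b <- res$gene[res$significant & res$log2fc < 0]
    up[hit_a, a] <- up[hit_a, a] + 1L
    up[hit_b, b] <- up[hit_b, b] + 1L
  }
  need <- mparams$pairwise_fraction * (C - 1)
  markers <- lapply(types, function(tp)
    rownames(up)[up[, tp] > need])      # strictly more than the fraction
  names(markers) <- types
  attr(markers, "n_de") <- up
  markers
}

#' Cross-tabulate DE genes by the cell type they mark
#'
#' For each direction of each DE result, counts how many significant genes
#' belong to each marker set; a gene marking several types increments each
#' of those sets.
#'
#' @param de_results named list of `DEResult` (name = tested cell type).
#' @param markers named list of marker gene sets (as from [find_markers()]).
#' @return data.frame: tested_type, direction (`up`/`down`), marker_type,
#'   n_genes.
#' @export
de_by_marker_identity <- function(de_results, markers) {
  rows <- list()
  for (tp in names(de_results)) {
    res <- de_results[[tp]]
    for (dir in c(1, -1)) {
      genes <- res$gene[res$significant & res$direction == dir]
      for (mk in names(markers)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tested_type = tp, direction = if (dir > 0) "up" else "down",
          marker_type = mk,
          n_genes = sum(genes %in% markers[[mk]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize DE results over user-supplied gene sets
#'
#' Restricts DE output (e.g. one result per cell type) to the supplied gene
#' lists — Hox clusters, pluripotency markers, extra-embryonic markers,
#' imprinted or germline genes, provided as plain lists — reporting per-set
#' up/down counts and a per-gene log2FC table (one row per set gene, one
#' column per tested cell type). Set genes absent from the tested family are
#' reported as untested, never as zeros.
#'
#' @param de_results named list of `DEResult` (name = cell type).
#' @param gene_sets named list of gene-id vectors.
#' @return list with `set_counts` (set, cell_type, n_up, n_down, n_untested),
#'   `log2fc` (data.frame: set, gene, one column per cell type) and
#'   `untested` (named list per set).
#' @export
gene_set_summary <- function(de_results, gene_sets) {
  types <- names(de_results)
  counts <- list(); fc_rows <- list(); untested <- list()
  for (s in names(gene_sets)) {
    genes <- gene_sets[[s]]
    tested_any <- unique(unlist(lapply(de_results, function(r) r$gene)))
    untested[[s]] <- setdiff(genes, tested_any)
    fc <- data.frame(set = s, gene = genes, stringsAsFactors = FALSE)
    for (tp in types) {
      r <- de_results[[tp]]
      i <- match(genes, r$gene)
      fc[[tp]] <- r$log2fc[i]
      counts[[length(counts) + 1L]] <- data.frame(
        set = s, cell_type = tp,
        n_up = sum(r$significant[i] & r$direction[i] > 0, na.rm = TRUE),
        n_down = sum(r$significant[i] & r$direction[i] < 0, na.rm = TRUE),
        n_untested = sum(is.na(i)),
        stringsAsFactors = FALSE)
    }
    fc_rows[[s]] <- fc
  }
  list(set_counts = do.call(rbind, counts),
       log2fc = do.call(rbind, fc_rows),
       untested = untested)
}
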