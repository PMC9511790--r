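#' Simulate RNA expression for trajectory cells
#'
#' The RNA half of the coupled trajectory fixture: a subset of genes changes
#' expression log-linearly in latent time (slopes drawn once per
#' simulation), including a strongly increasing anchor gene (an embryonic
#' haemoglobin stand-in) used downstream to orient pseudotime; the remaining
#' genes are flat. Counts are negative binomial as in [atlas_spec()].
#'
#' @param time latent time per cell, in [0, 1].
#' @param cell_ids cell identifiers (couple these to the bisulfite cells of
#'   [simulate_nmt_cells()] to obtain joint RNA+CpG+GpC profiles).
#' @param n_genes,n_dynamic total and time-dependent gene counts.
#' @param slope_sd sd of dynamic genes' log2 slopes.
#' @param anchor_log2fc anchor gene's log2 change from time 0 to 1.
#' @param library_size_mean,dispersion negative-binomial parameters.
#' @param seed integer seed.
#' @return list: `counts` (a `CountMatrix`; the anchor gene is
#'   `"anchor_gene"`), `anchor_gene`, `slopes` (per-gene log2 slopes, ground
#'   truth).
#' @export
simulate_trajectory_rna <- function(time, cell_ids = NULL,
                                    n_genes = 300, n_dynamic = 100,
                                    slope_sd = 1.5, anchor_log2fc = 4,
                                    library_size_mean = 5000,
                                    dispersion = 0.1, seed = 1L) {
  assert_in_range(time, 0, 1, "latent time")
  n_cells <- length(time)
  cell_ids <- cell_ids %||% sprintf("traj_cell_%04d", seq_len(n_cells))
  set.seed(seed)
  gene_ids <- c("anchor_gene", sprintf("tgene_%04d", seq_len(n_genes - 1)))
  base <- stats::rgamma(n_genes, shape = 0.8, rate = 1) + 0.05
  slopes <- numeric(n_genes)
  dyn <- 1L + sample.int(n_genes - 1L, n_dynamic - 1L)
  slopes[dyn] <- stats::rnorm(n_dynamic - 1L, 0, slope_sd)
  slopes[1] <- anchor_log2fc
  mu_rel <- outer(time, slopes, function(t, s) 2^(s * t))
  mu_rel <- sweep(mu_rel, 2, base, "*")
  mu <- mu_rel / rowSums(mu_rel) * library_size_mean
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu,
                                  size = 1 / dispersion),
                   nrow = n_cells, dimnames = list(cell_ids, gene_ids))
  list(counts = count_matrix(Matrix::Matrix(counts, sparse = TRUE)),
       anchor_gene = "anchor_gene",
       slopes = stats::setNames(slopes, gene_ids))
}
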