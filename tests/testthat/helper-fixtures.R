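# Shared synthetic fixtures, built once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(name, compute) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- compute()
  .fixture_cache[[name]]
}

# Small atlas + unperturbed query for mapping tests (3 well-separated types).
small_map_fixture <- function() memo_fixture("small_map", function() {
  spec <- atlas_spec(n_cell_types = 3, n_genes = 300, n_markers_per_type = 25,
                     stages = "E8.5",
                     stage_composition = matrix(1 / 3, 1, 3),
                     n_embryos_per_stage = 4, seed = 421L)
  atlas <- simulate_atlas(spec, n_cells = 900)
  query <- simulate_query_embryos(spec, perturbation_spec(), n_embryos = 3,
                                  n_cells_per_embryo = 100, genotype = "KO",
                                  seed = 422L)
  list(spec = spec, atlas = atlas, query = query)
})

# Full-size atlas + query cohort used by the label-transfer benchmark.
big_map_fixture <- function() memo_fixture("big_map", function() {
  spec <- atlas_spec(seed = 101L)
  atlas <- simulate_atlas(spec, n_cells = 5000)
  query <- simulate_query_embryos(spec, perturbation_spec(), n_embryos = 10,
                                  n_cells_per_embryo = 200,
                                  genotype = "Dnmt1KO", seed = 102L)
  params <- mapping_params(n_hvgs = 500, n_pcs = 50)
  res <- suppressWarnings(map_to_reference(atlas$counts, query$counts,
                                           atlas$annotation$cell_type,
                                           params))
  list(spec = spec, atlas = atlas, query = query, params = params,
       result = res)
})

# Coupled CpG/GpC cells with matched RNA: a cohort spanning the whole
# differentiation trajectory (for pseudotime and methylation curves) and a
# sorted late-trajectory "erythroid" cohort of 60 cells per genotype (for
# feature profiles and WT-vs-TKO comparisons).
nmt_fixture <- function() memo_fixture("nmt", function() {
  espec <- epigenome_spec(seed = 77L)
  fs <- simulate_feature_set(espec, c(promoters = 60,
                                      erythroid_enhancers = 60,
                                      other_enhancers = 60))
  n <- 60
  traj_time <- c(stats::ppoints(n), stats::ppoints(n))
  traj_geno <- rep(c("WT", "TetTKO"), each = n)
  traj_nmt <- simulate_nmt_cells(espec, fs, traj_time, traj_geno)
  rna <- simulate_trajectory_rna(traj_time,
                                 cell_ids = traj_nmt$truth$cell_id,
                                 seed = 78L)
  espec_ery <- epigenome_spec(seed = 79L)
  ery_time <- rep(0.85 + 0.15 * stats::ppoints(60), 2)
  ery_geno <- rep(c("WT", "TetTKO"), each = 60)
  ery_nmt <- simulate_nmt_cells(espec_ery, fs, ery_time, ery_geno)
  list(espec = espec, fs = fs,
       traj = list(time = traj_time, genotype = traj_geno, nmt = traj_nmt,
                   rna = rna),
       ery = list(time = ery_time, genotype = ery_geno, nmt = ery_nmt))
})

# Pseudobulk NB sampler: two groups of n samples, optional planted log2 fold
# change on the first genes.
simulate_pseudobulk <- function(n_genes = 500, mu = 200, dispersion = 0.05,
                                n = 4, lfc_genes = integer(0), lfc = 0,
                                seed = 1) {
  set.seed(seed)
  base <- stats::rgamma(n_genes, 2, scale = mu / 2)
  m <- sapply(seq_len(2 * n), function(j) {
    mj <- base
    if (j > n && length(lfc_genes)) mj[lfc_genes] <- mj[lfc_genes] * 2^lfc
    stats::rnbinom(n_genes, mu = mj, size = 1 / dispersion)
  })
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%d", seq_len(2 * n))
  structure(list(counts = m, factor = median_of_ratios(m),
                 group = stats::setNames(rep(c("WT", "KO"), each = n),
                                         colnames(m)),
                 n_cells = stats::setNames(rep(50, 2 * n), colnames(m))),
            class = "PseudobulkMatrix")
}

# Brute-force Benjamini-Hochberg step-up, independent of p.adjust.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Direct tricube weighted-least-squares fit at one point (LOESS oracle).
wls_tricube_oracle <- function(x, y, span, x0) {
  n <- length(x)
  q <- floor(span * n)
  d <- abs(x - x0)
  dmax <- sort(d)[q]
  w <- (1 - pmin(d / dmax, 1)^3)^3
  stats::lm.wfit(cbind(1, x - x0), y, w)$coefficients[1]
}

# Random methylation calls + random features for aggregation oracle tests.
random_agg_fixture <- function(seed, n_sites = 1000, n_features = 50) {
  set.seed(seed)
  pos <- sort(sample.int(50000, n_sites))
  calls <- suppressWarnings(meth_call_set(
    data.frame(chrom = "chr1", pos = pos,
               meth = stats::rbinom(n_sites, 2, 0.5),
               unmeth = stats::rbinom(n_sites, 2, 0.5))))
  st <- sample.int(49000, n_features)
  fs <- feature_set("chr1", st, st + sample(100:1000, n_features),
                    class_label = "random")
  list(calls = calls, fs = fs, starts = st)
}

# Brute-force per-site interval scan oracle for aggregate_features.
aggregate_oracle <- function(calls, fs) {
  dt <- calls$calls
  b <- as.numeric(dt$meth / (dt$meth + dt$unmeth) >= 0.5)
  out <- list()
  for (i in seq_along(fs)) {
    inside <- as.character(GenomicRanges::seqnames(fs))[i] == dt$chrom &
      dt$pos >= GenomicRanges::start(fs)[i] &
      dt$pos <= GenomicRanges::end(fs)[i]
    if (any(inside))
      out[[length(out) + 1L]] <- data.frame(
        feature = S4Vectors::mcols(fs)$name[i],
        n_meth = sum(b[inside]), n_total = sum(inside))
  }
  do.call(rbind, out)
}

# Poisson reference set with genes planted as high in chosen cell types;
# boosts: named list gene -> character vector of boosted types.
marker_fixture <- function(n_types, boosts, seed = 62) {
  set.seed(seed)
  types <- LETTERS[seq_len(n_types)]
  genes <- c(names(boosts), sprintf("bg%02d", 1:30))
  cells <- list(); anns <- list()
  for (tp in types) for (e in 1:3) {
    n <- 20
    mu <- rep(25, length(genes))
    names(mu) <- genes
    for (g in names(boosts)) if (tp %in% boosts[[g]]) mu[g] <- 25 * 16
    m <- matrix(stats::rpois(n * length(genes), rep(mu, each = n)), n,
                dimnames = list(sprintf("%s_e%d_c%02d", tp, e, seq_len(n)),
                                genes))
    cells[[length(cells) + 1L]] <- m
    anns[[length(anns) + 1L]] <- data.frame(
      cell_id = rownames(m), embryo_id = sprintf("%s_e%d", tp, e),
      genotype = "WT", cell_type = tp, stringsAsFactors = FALSE)
  }
  list(cm = count_matrix(do.call(rbind, cells)),
       ann = do.call(rbind, anns))
}

tiny_pipeline_config <- function(out_dir, seed = 5L) {
  cfg <- validate_config(quiet = TRUE)
  cfg$seed <- seed
  cfg$out_dir <- out_dir
  cfg$simulate$n_atlas_cells <- 400L
  cfg$simulate$n_genes <- 300L
  cfg$simulate$n_wt_embryos <- 3L
  cfg$simulate$n_ko_embryos <- 3L
  cfg$simulate$n_cells_per_embryo <- 80L
  cfg$simulate$n_traj_wt <- 20L
  cfg$simulate$n_traj_tko <- 20L
  cfg$simulate$features_per_class <- 6L
  cfg$mapping$n_hvgs <- 200L
  cfg$mapping$n_pcs <- 20L
  cfg$de$min_cells_per_sample <- 3L
  cfg
}
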