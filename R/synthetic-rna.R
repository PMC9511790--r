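#' Specification of a synthetic reference atlas
#'
#' Defines the study conditions emulated by the RNA generators: a labelled,
#' multi-stage reference atlas of embryo cells. Counts are negative binomial
#' with gene-level means and a shared dispersion (the same model family the
#' differential-expression stage assumes), markers of each cell type are
#' up-shifted by a fixed log2 effect, and per-cell sequencing depth is
#' log-normal so size-factor normalization has planted depth differences to
#' remove.
#'
#' @param n_cell_types number of cell types.
#' @param n_genes number of genes.
#' @param n_markers_per_type number of marker genes planted per cell type;
#'   marker sets are disjoint.
#' @param stages ordered developmental stage labels.
#' @param stage_composition stages x cell-types matrix of proportions, each
#'   row summing to 1. The default drifts from early-dominant to
#'   late-dominant types so that stages are separable by composition alone.
#' @param n_embryos_per_stage reference embryos per stage.
#' @param library_size_mean mean per-cell total count.
#' @param library_size_sdlog sdlog of the log-normal per-cell depth factor.
#' @param nb_dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param marker_log2fc log2 up-shift of a type's markers in that type.
#' @param batch_sdlog sdlog of the per-gene log-normal batch scaling applied
#'   to query (not atlas) cells, giving the batch-correction stage real work.
#' @param seed integer seed; all generators are bit-reproducible under it.
#' @return an object of class `AtlasSpec`.
#' @export
atlas_spec <- function(n_cell_types = 5,
                       n_genes = 800,
                       n_markers_per_type = 20,
                       stages = c("E7.5", "E8.0", "E8.5"),
                       stage_composition = NULL,
                       n_embryos_per_stage = 6,
                       library_size_mean = 2500,
                       library_size_sdlog = 0.3,
                       nb_dispersion = 0.1,
                       marker_log2fc = 3,
                       batch_sdlog = 0.25,
                       seed = 1L) {
  if (n_markers_per_type * n_cell_types > n_genes)
    abort("need n_markers_per_type * n_cell_types <= n_genes")
  types <- default_cell_types(n_cell_types)
  if (is.null(stage_composition))
    stage_composition <- default_stage_composition(length(stages), n_cell_types)
  stage_composition <- as.matrix(stage_composition)
  if (nrow(stage_composition) != length(stages) ||
      ncol(stage_composition) != n_cell_types)
    abort("stage_composition must be %d stages x %d cell types",
          length(stages), n_cell_types)
  if (any(stage_composition < 0) ||
      any(abs(rowSums(stage_composition) - 1) > 1e-9))
    abort("stage_composition rows must be non-negative and sum to 1")
  dimnames(stage_composition) <- list(stages, types)
  structure(list(n_cell_types = n_cell_types, n_genes = n_genes,
                 n_markers_per_type = n_markers_per_type,
                 stages = stages, cell_types = types,
                 stage_composition = stage_composition,
                 n_embryos_per_stage = n_embryos_per_stage,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 nb_dispersion = nb_dispersion,
                 marker_log2fc = marker_log2fc,
                 batch_sdlog = batch_sdlog,
                 seed = as.integer(seed)),
            class = "AtlasSpec")
}

default_cell_types <- function(n) {
  base <- c("Epiblast", "Neural_crest", "Erythroid", "Mixed_mesoderm",
            "Surface_ectoderm", "Haematoendothelial", "Gut", "Allantois")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("type_%d", seq_len(n - length(base))))
}

# early types fade out, late types fade in, middle types stay flat
default_stage_composition <- function(n_stages, n_types) {
  w <- sapply(seq_len(n_types), function(k) {
    centre <- (k - 1) / max(1, n_types - 1)      # type's "preferred" time
    t <- if (n_stages == 1) 0.5 else (seq_len(n_stages) - 1) / (n_stages - 1)
    0.15 + exp(-((t - centre) / 0.6)^2)
  })
  sweep(w, 1, rowSums(w), "/")
}

#' Gene-level mean expression profiles of an atlas spec
#'
#' Baseline relative expression is gamma-distributed across genes; each cell
#' type's markers are multiplied by `2^marker_log2fc` and the profile is
#' renormalized to sum to 1 (so expected totals equal the library size).
#' Deterministic given the spec seed.
#'
#' @param spec an `AtlasSpec`.
#' @return list with `profiles` (cell types x genes matrix of relative
#'   expression, rows sum to 1), `markers` (named list of marker gene ids per
#'   type) and `gene_ids`.
#' @export
atlas_profiles <- function(spec) {
  set.seed(spec$seed)
  gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
  base <- stats::rgamma(spec$n_genes, shape = 0.6, rate = 1) + 0.02
  markers <- list()
  profiles <- matrix(rep(base, each = spec$n_cell_types),
                     nrow = spec$n_cell_types,
                     dimnames = list(spec$cell_types, gene_ids))
  for (k in seq_len(spec$n_cell_types)) {
    idx <- ((k - 1) * spec$n_markers_per_type) + seq_len(spec$n_markers_per_type)
    markers[[spec$cell_types[k]]] <- gene_ids[idx]
    profiles[k, idx] <- profiles[k, idx] * 2^spec$marker_log2fc
  }
  profiles <- sweep(profiles, 1, rowSums(profiles), "/")
  list(profiles = profiles, markers = markers, gene_ids = gene_ids)
}

# draw NB counts for cells given type profiles; returns sparse cells x genes
draw_counts <- function(profiles, type_idx, depth, dispersion, cell_ids,
                        gene_scale = NULL) {
  n_cells <- length(type_idx); n_genes <- ncol(profiles)
  mu <- profiles[type_idx, , drop = FALSE] * depth
  if (!is.null(gene_scale)) mu <- sweep(mu, 2, gene_scale, "*")
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu,
                                  size = 1 / dispersion),
                   nrow = n_cells,
                   dimnames = list(cell_ids, colnames(profiles)))
  count_matrix(Matrix::Matrix(counts, sparse = TRUE))
}

#' Simulate a labelled multi-stage reference atlas
#'
#' Each cell is assigned to an embryo (embryos are split evenly across
#' stages), draws its cell type from the stage's composition vector and its
#' counts from the negative-binomial model of [atlas_spec()].
#'
#' @param spec an `AtlasSpec`.
#' @param n_cells total number of atlas cells.
#' @return list with `counts` (a `CountMatrix`), `annotation` (per-cell
#'   data.frame with embryo, stage and true cell type), `embryos` (embryo ->
#'   stage table) and `markers` (planted marker sets, the hidden ground truth).
#' @export
simulate_atlas <- function(spec, n_cells = 3000) {
  pr <- atlas_profiles(spec)              # also seeds the RNG
  n_stages <- length(spec$stages)
  n_embryos <- n_stages * spec$n_embryos_per_stage
  embryo_stage <- rep(seq_len(n_stages), each = spec$n_embryos_per_stage)
  embryo_ids <- sprintf("atlas_embryo_%02d", seq_len(n_embryos))
  cell_embryo <- sort(rep_len(seq_len(n_embryos), n_cells))
  stage_idx <- embryo_stage[cell_embryo]
  type_idx <- vapply(stage_idx, function(s)
    sample.int(spec$n_cell_types, 1L, prob = spec$stage_composition[s, ]), 1L)
  depth <- stats::rlnorm(n_cells,
                         meanlog = log(spec$library_size_mean) -
                           spec$library_size_sdlog^2 / 2,
                         sdlog = spec$library_size_sdlog)
  ids <- sprintf("atlas_cell_%05d", seq_len(n_cells))
  cm <- draw_counts(pr$profiles, type_idx, depth, spec$nb_dispersion, ids)
  ann <- data.frame(cell_id = ids,
                    embryo_id = embryo_ids[cell_embryo],
                    genotype = "WT",
                    stage_label = spec$stages[stage_idx],
                    platform = "droplet",
                    cell_type = spec$cell_types[type_idx],
                    host_flag = FALSE,
                    stringsAsFactors = FALSE)
  list(counts = cm, annotation = ann,
       embryos = data.frame(embryo_id = embryo_ids,
                            stage = spec$stages[embryo_stage],
                            stringsAsFactors = FALSE),
       markers = pr$markers)
}

#' Specification of a planted perturbation for query embryos
#'
#' @param fold_changes named numeric vector: multiplier applied to the
#'   baseline proportion of each named cell type (the vector is then
#'   renormalized to sum to 1).
#' @param dysregulated_genes data.frame with columns `gene`, `log2fc` and
#'   `cell_type` (comma-separated list of affected types, or `"all"`).
#' @param delay_shift non-negative integer; number of stages of developmental
#'   delay — the embryo draws its composition from that many stages earlier.
#' @return an object of class `PerturbationSpec`.
#' @export
perturbation_spec <- function(fold_changes = numeric(0),
                              dysregulated_genes = NULL,
                              delay_shift = 0L) {
  if (length(fold_changes) && is.null(names(fold_changes)))
    abort("fold_changes must be named by cell type")
  structure(list(fold_changes = fold_changes,
                 dysregulated_genes = dysregulated_genes,
                 delay_shift = as.integer(delay_shift)),
            class = "PerturbationSpec")
}

#' Perturbed, renormalized composition vector
#'
#' Applies a perturbation's proportion fold changes and delay shift to an
#' atlas spec's composition at the given stage. Exposed so tests can use the
#' closed-form planted proportions.
#'
#' @param spec an `AtlasSpec`; @param perturbation a `PerturbationSpec`;
#' @param stage stage label the embryos notionally belong to.
#' @return named proportion vector summing to 1.
#' @export
perturbed_composition <- function(spec, perturbation, stage) {
  s <- match(stage, spec$stages)
  if (is.na(s)) abort("unknown stage '%s'", stage)
  s <- max(1L, s - perturbation$delay_shift)
  comp <- spec$stage_composition[s, ]
  fc <- perturbation$fold_changes
  if (length(fc)) {
    unknown <- setdiff(names(fc), spec$cell_types)
    if (length(unknown))
      abort("fold_changes names unknown cell type(s): %s",
            paste(unknown, collapse = ", "))
    comp[names(fc)] <- comp[names(fc)] * fc
  }
  comp / sum(comp)
}

#' Simulate perturbed query embryos
#'
#' Query cells carry a per-gene log-normal batch scaling (drawn once per
#' simulation) relative to the atlas, composition follows the perturbed,
#' renormalized stage composition, and dysregulated genes are shifted only in
#' their affected cell types. The true cell type of every cell is recorded in
#' the annotation — downstream label transfer is evaluated against it.
#'
#' @param spec an `AtlasSpec`; @param perturbation a `PerturbationSpec`.
#' @param n_embryos,n_cells_per_embryo query cohort size.
#' @param genotype genotype label recorded for the cohort.
#' @param stage stage the embryos were collected at (default: last stage).
#' @param seed seed for this cohort; defaults to `spec$seed + 1`.
#' @param batch if `FALSE`, suppress the planted batch effect.
#' @return list with `counts`, `annotation` (including hidden truth columns),
#'   and `batch_factors` (the per-gene scaling, ground truth).
#' @export
simulate_query_embryos <- function(spec, perturbation = perturbation_spec(),
                                   n_embryos = 10, n_cells_per_embryo = 200,
                                   genotype = "Dnmt1KO", stage = NULL,
                                   seed = NULL, batch = TRUE) {
  stage <- stage %||% spec$stages[length(spec$stages)]
  comp <- perturbed_composition(spec, perturbation, stage)
  pr <- atlas_profiles(spec)              # deterministic from spec seed
  profiles <- pr$profiles
  dg <- perturbation$dysregulated_genes
  if (!is.null(dg) && nrow(dg)) {
    for (i in seq_len(nrow(dg))) {
      g <- match(dg$gene[i], colnames(profiles))
      if (is.na(g)) abort("dysregulated gene '%s' not in gene set", dg$gene[i])
      tt <- if (identical(dg$cell_type[i], "all")) spec$cell_types else
        strsplit(dg$cell_type[i], ",")[[1]]
      profiles[tt, g] <- profiles[tt, g] * 2^dg$log2fc[i]
    }
  }
  set.seed(seed %||% (spec$seed + 1L))
  gene_scale <- if (batch)
    stats::rlnorm(spec$n_genes, 0, spec$batch_sdlog) else NULL
  n_cells <- n_embryos * n_cells_per_embryo
  type_idx <- sample.int(spec$n_cell_types, n_cells, replace = TRUE,
                         prob = comp)
  depth <- stats::rlnorm(n_cells,
                         meanlog = log(spec$library_size_mean) -
                           spec$library_size_sdlog^2 / 2,
                         sdlog = spec$library_size_sdlog)
  ids <- sprintf("query_%s_cell_%05d", tolower(genotype), seq_len(n_cells))
  cm <- draw_counts(profiles, type_idx, depth, spec$nb_dispersion, ids,
                    gene_scale = gene_scale)
  ann <- data.frame(cell_id = ids,
                    embryo_id = sprintf("%s_embryo_%02d", tolower(genotype),
                                        rep(seq_len(n_embryos),
                                            each = n_cells_per_embryo)),
                    genotype = genotype,
                    stage_label = NA_character_,
                    platform = "droplet",
                    cell_type = spec$cell_types[type_idx],
                    host_flag = FALSE,
                    stringsAsFactors = FALSE)
  list(counts = cm, annotation = ann, batch_factors = gene_scale)
}
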