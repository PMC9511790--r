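pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "scembryo_output",
    simulate = list(
      n_cell_types = 5L, n_genes = 600L, n_markers_per_type = 20L,
      n_atlas_cells = 2000L,
      n_wt_embryos = 6L, n_ko_embryos = 6L, n_cells_per_embryo = 150L,
      depleted_type = "Erythroid", depletion = 0.25,
      n_traj_wt = 40L, n_traj_tko = 40L, features_per_class = 12L,
      feature_width = 1000L),
    qc = list(
      droplet = list(min_counts = 1500, max_mito_pct = 30, max_ribo_pct = 35),
      plate = list(min_counts = 4000, max_mito_pct = 10, max_ribo_pct = 20),
      meth_min_sites = 5000, acc_min_sites = 10000,
      meth_global_min = 50, acc_global_range = c(10, 40)),
    mapping = list(n_hvgs = 2000L, n_pcs = 50L, k_neighbors = 30L,
                   mnn_k = 20L, mnn_sigma = 0.1),
    de = list(fdr = 0.01, min_abs_log2fc = 1, min_cells_per_sample = 10L,
              min_samples_per_group = 2L),
    markers = list(pairwise_fraction = 0.75),
    profile = list(window_size = 50L, flank = 2000L),
    staging = list(pseudocount = 1, n_pcs = NULL),
    pseudotime = list(span = 0.5, kernel_scale = 5L),
    gene_set_files = list())
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort("unknown configuration key: %s%s", path, unknown[1])
  for (k in names(user)) {
    key <- paste0(path, k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) abort("key %s must be a mapping", key)
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(key, "."))
    } else {
      v <- user[[k]]
      if (!is.null(defaults[[k]]) && is.numeric(defaults[[k]]) &&
          !is.numeric(v))
        abort("key %s must be numeric", key)
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML document, fills every default (all study constants — the
#' per-platform QC gates, k = 30 voting neighbours, 1% FDR with
#' |log2FC| >= 1, the 75% marker rule, the bisulfite site minima and global
#' gates, 50 bp profile windows with 2 kb flanks — are named, overridable
#' defaults), rejects unknown keys, checks types and ranges, and echoes the
#' effective parameters.
#'
#' @param path YAML file; an empty file yields all defaults. `NULL` gives
#'   the defaults directly.
#' @param quiet suppress the parameter echo.
#' @return a validated configuration list of class `PipelineConfig`.
#' @export
validate_config <- function(path = NULL, quiet = FALSE) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(pipeline_defaults(), user)
  # range/type checks via the parameter constructors
  de_params(cfg$de$fdr, cfg$de$min_abs_log2fc, cfg$de$min_cells_per_sample,
            cfg$de$min_samples_per_group)
  marker_params(cfg$markers$pairwise_fraction)
  profile_params(cfg$profile$window_size, cfg$profile$flank)
  mapping_params(cfg$mapping$n_hvgs, cfg$mapping$n_pcs,
                 cfg$mapping$k_neighbors, cfg$mapping$mnn_k,
                 cfg$mapping$mnn_sigma)
  config_qc_params(cfg)
  for (f in unlist(cfg$gene_set_files))
    if (!file.exists(f)) abort("gene set file does not exist: %s", f)
  if (!quiet)
    message("effective configuration:\n",
            paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
                  collapse = "\n"))
  structure(cfg, class = "PipelineConfig")
}

config_qc_params <- function(cfg) {
  qc_params(
    min_counts = c(droplet = cfg$qc$droplet$min_counts,
                   plate = cfg$qc$plate$min_counts),
    max_mito_pct = c(droplet = cfg$qc$droplet$max_mito_pct,
                     plate = cfg$qc$plate$max_mito_pct),
    max_ribo_pct = c(droplet = cfg$qc$droplet$max_ribo_pct,
                     plate = cfg$qc$plate$max_ribo_pct),
    meth_min_sites = cfg$qc$meth_min_sites,
    acc_min_sites = cfg$qc$acc_min_sites,
    meth_global_min = cfg$qc$meth_global_min,
    acc_global_range = cfg$qc$acc_global_range)
}

stage_hash <- function(cfg, stage) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(stage = stage, seed = cfg$seed, cfg = unclass(cfg)), f,
          version = 2)
  unname(tools::md5sum(f)[[1]])
}

#' Run the full knockout-versus-wildtype pipeline on synthetic fixtures
#'
#' Chains the stages in the study's order — simulate fixtures, QC and
#' normalization, atlas mapping and label transfer, composition and
#' staging, pseudobulk differential expression with markers, epigenome
#' quantification and pseudotime — writing each stage's tables as
#' deterministically formatted TSV plus a JSON manifest with a parameter
#' hash, output checksums and row counts per stage. A stage is skipped on
#' re-run when its manifest hash matches and its outputs are intact, so
#' runs are resumable; changing the seed (or any parameter) invalidates the
#' hashes and triggers recomputation. Any stage error aborts with the stage
#' name.
#'
#' @param config a `PipelineConfig` from [validate_config()].
#' @param force recompute everything, ignoring existing outputs.
#' @return the manifest (invisibly).
#' @export
run_pipeline <- function(config = validate_config(quiet = TRUE),
                         force = FALSE) {
  cfg <- config
  sim <- cfg$simulate
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (!force && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  state <- new.env(parent = emptyenv())

  memo <- function(name, compute) {
    if (is.null(state[[name]])) state[[name]] <- compute()
    state[[name]]
  }
  spec <- atlas_spec(n_cell_types = sim$n_cell_types, n_genes = sim$n_genes,
                     n_markers_per_type = sim$n_markers_per_type,
                     seed = cfg$seed)
  get_atlas <- function() memo("atlas", function()
    simulate_atlas(spec, n_cells = sim$n_atlas_cells))
  get_query <- function() memo("query", function() {
    wt <- simulate_query_embryos(
      spec, perturbation_spec(), n_embryos = sim$n_wt_embryos,
      n_cells_per_embryo = sim$n_cells_per_embryo, genotype = "WT",
      seed = cfg$seed + 101L)
    ko <- simulate_query_embryos(
      spec, perturbation_spec(
        fold_changes = stats::setNames(sim$depletion, sim$depleted_type)),
      n_embryos = sim$n_ko_embryos,
      n_cells_per_embryo = sim$n_cells_per_embryo, genotype = "TetTKO",
      seed = cfg$seed + 202L)
    list(counts = count_matrix(rbind(wt$counts$counts, ko$counts$counts),
                               wt$counts$gene_names),
         annotation = rbind(wt$annotation, ko$annotation))
  })
  get_mapping <- function() memo("mapping", function() {
    mp <- mapping_params(cfg$mapping$n_hvgs, cfg$mapping$n_pcs,
                         cfg$mapping$k_neighbors, cfg$mapping$mnn_k,
                         cfg$mapping$mnn_sigma)
    suppressWarnings(map_to_reference(
      get_atlas()$counts, get_query()$counts,
      get_atlas()$annotation$cell_type, mp))
  })
  get_mapped_ann <- function() memo("mapped_ann", function() {
    ann <- get_query()$annotation
    asg <- get_mapping()$assignment
    ann$cell_type <- asg$cell_type[match(ann$cell_id, asg$cell_id)]
    ann
  })

  fresh <- function(stage, files) {
    h <- stage_hash(cfg, stage)
    m <- manifest[[stage]]
    ok <- !force && !is.null(m) && identical(m$hash, h) &&
      all(file.exists(file.path(cfg$out_dir, files))) &&
      all(vapply(m$outputs, function(o)
        identical(unname(tools::md5sum(file.path(cfg$out_dir,
                                                 o$file))[[1]]), o$md5),
        TRUE))
    !isTRUE(ok)
  }
  record <- function(stage, files) {
    manifest[[stage]] <<- list(
      hash = stage_hash(cfg, stage),
      seed = cfg$seed,
      outputs = lapply(files, function(f) {
        p <- file.path(cfg$out_dir, f)
        list(file = f, md5 = unname(tools::md5sum(p)[[1]]),
             rows = length(readLines(p)) - 1L)
      }))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(stage, files, compute) {
    if (fresh(stage, files)) {
      message("[", stage, "] computing")
      tryCatch(compute(),
               error = function(e) abort("stage '%s' failed: %s", stage,
                                         conditionMessage(e)))
      record(stage, files)
    } else message("[", stage, "] up to date; skipping")
  }

  ## -- fixtures ------------------------------------------------------------
  run_stage("fixtures", c("atlas_annotation.tsv", "query_annotation.tsv"),
            function() {
    write_counts(get_atlas()$counts, file.path(cfg$out_dir, "atlas_counts"))
    write_tsv_det(get_atlas()$annotation,
                  file.path(cfg$out_dir, "atlas_annotation.tsv"))
    write_tsv_det(get_query()$annotation,
                  file.path(cfg$out_dir, "query_annotation.tsv"))
  })

  ## -- qc + normalization --------------------------------------------------
  run_stage("qc_norm", c("qc_rna.tsv", "size_factors.tsv"), function() {
    qp <- config_qc_params(cfg)
    qc <- suppressWarnings(rbind(
      qc_rna(get_atlas()$counts, params = qp, platform = "droplet"),
      qc_rna(get_query()$counts, params = qp, platform = "droplet")))
    write_tsv_det(qc, file.path(cfg$out_dir, "qc_rna.tsv"))
    sf <- size_factors(get_query()$counts, "pooled")
    write_tsv_det(data.frame(cell_id = names(sf$size_factor),
                             size_factor = as.numeric(sf$size_factor),
                             method = sf$method),
                  file.path(cfg$out_dir, "size_factors.tsv"))
  })

  ## -- mapping -------------------------------------------------------------
  run_stage("mapping", "mapping.tsv", function() {
    res <- get_mapping()
    tab <- res$assignment
    tab$top_neighbors <- apply(res$neighbors[, seq_len(min(5, res$k)),
                                             drop = FALSE], 1,
                               paste, collapse = ",")
    write_tsv_det(tab, file.path(cfg$out_dir, "mapping.tsv"))
  })

  ## -- composition + staging -----------------------------------------------
  run_stage("composition", c("proportions.tsv", "log2_shift.tsv",
                             "staging.tsv"), function() {
    tab <- proportions(get_mapped_ann(),
                       pseudocount = cfg$staging$pseudocount,
                       cell_types = spec$cell_types)
    pm <- tab$proportions
    write_tsv_det(data.frame(embryo_id = rownames(pm),
                             genotype = tab$embryo_info$genotype, pm,
                             check.names = FALSE),
                  file.path(cfg$out_dir, "proportions.tsv"))
    write_tsv_det(log2_shift(tab, "ko_vs_wt_mean"),
                  file.path(cfg$out_dir, "log2_shift.tsv"))
    ref_tab <- proportions(get_atlas()$annotation,
                           pseudocount = cfg$staging$pseudocount,
                           cell_types = spec$cell_types)
    emb <- get_atlas()$embryos
    st <- stage_embryos(tab, ref_tab,
                        emb$stage[match(rownames(ref_tab$proportions),
                                        emb$embryo_id)],
                        n_pcs = cfg$staging$n_pcs)
    write_tsv_det(data.frame(embryo_id = rownames(st$scores), st$scores,
                             stage = st$stage, check.names = FALSE),
                  file.path(cfg$out_dir, "staging.tsv"))
  })

  ## -- differential expression + markers ------------------------------------
  run_stage("de", c("de_results.tsv", "markers.tsv", "de_by_marker.tsv"),
            function() {
    dp <- de_params(cfg$de$fdr, cfg$de$min_abs_log2fc,
                    cfg$de$min_cells_per_sample, cfg$de$min_samples_per_group)
    de_list <- list()
    for (tp in spec$cell_types) {
      res <- tryCatch({
        pb <- make_pseudobulk(get_query()$counts, get_mapped_ann(),
                              cell_type = tp,
                              min_cells_per_sample = dp$min_cells_per_sample)
        if (length(unique(pb$group)) < 2 ||
            any(table(pb$group) < dp$min_samples_per_group)) {
          message("  [de] skipping ", tp, ": too few samples per group")
          NULL
        } else nb_test(pb, dp, contrast = c("WT", "TetTKO"))
      }, error = function(e) {
        message("  [de] skipping ", tp, ": ", conditionMessage(e)); NULL
      })
      if (!is.null(res)) de_list[[tp]] <- res
    }
    de_tab <- do.call(rbind, lapply(names(de_list), function(tp)
      cbind(cell_type = tp, de_list[[tp]])))
    if (is.null(de_tab))
      de_tab <- data.frame(cell_type = character(0), gene = character(0),
                           log2fc = numeric(0), dispersion = numeric(0),
                           stat = numeric(0), pvalue = numeric(0),
                           padj = numeric(0), significant = logical(0),
                           direction = numeric(0))
    write_tsv_det(de_tab, file.path(cfg$out_dir, "de_results.tsv"))
    mk <- find_markers(get_atlas()$counts, get_atlas()$annotation, dp,
                       marker_params(cfg$markers$pairwise_fraction))
    write_tsv_det(data.frame(
      cell_type = rep(names(mk), lengths(mk)),
      gene = unlist(mk, use.names = FALSE)),
      file.path(cfg$out_dir, "markers.tsv"))
    write_tsv_det(de_by_marker_identity(de_list, mk),
                  file.path(cfg$out_dir, "de_by_marker.tsv"))
  })

  ## -- epigenome + pseudotime ----------------------------------------------
  run_stage("epigenome", c("feature_rates.tsv", "profiles.tsv",
                           "epigenome_comparison.tsv", "pseudotime.tsv",
                           "methylation_curves.tsv"), function() {
    espec <- epigenome_spec(seed = cfg$seed + 303L)
    fs <- simulate_feature_set(
      espec, stats::setNames(rep(sim$features_per_class, 3),
                             espec$feature_classes$class),
      width = sim$feature_width)
    n1 <- sim$n_traj_wt; n2 <- sim$n_traj_tko
    time <- c(stats::ppoints(n1), stats::ppoints(n2))
    geno <- rep(c("WT", "TetTKO"), c(n1, n2))
    nmt <- simulate_nmt_cells(espec, fs, time, geno)
    frm <- feature_rate_matrix(nmt$cpg, fs)
    write_tsv_det(frm, file.path(cfg$out_dir, "feature_rates.tsv"))
    pp <- profile_params(cfg$profile$window_size, cfg$profile$flank)
    prof <- list()
    late <- nmt$truth$time >= 0.75
    for (g in c("WT", "TetTKO")) for (cl in espec$feature_classes$class) {
      cells <- which(nmt$truth$genotype == g & late)
      pr <- meth_profile(nmt$cpg[cells],
                         fs[S4Vectors::mcols(fs)$class == cl], pp)
      prof[[length(prof) + 1L]] <- cbind(genotype = g, class = cl,
                                         context = "CpG", pr)
    }
    write_tsv_det(do.call(rbind, prof), file.path(cfg$out_dir, "profiles.tsv"))
    groups <- split(nmt$truth$cell_id, nmt$truth$genotype)
    cmpr <- compare_groups(frm[frm$cell_id %in% nmt$truth$cell_id[late], ],
                           list(WT = groups$WT, TetTKO = groups$TetTKO))
    write_tsv_det(cmpr, file.path(cfg$out_dir, "epigenome_comparison.tsv"))
    rna <- simulate_trajectory_rna(time, cell_ids = nmt$truth$cell_id,
                                   seed = cfg$seed + 404L)
    lg <- normalized_matrix(rna$counts)
    dm <- diffusion_map(lg, n_components = 2,
                        kernel_scale = cfg$pseudotime$kernel_scale)
    pt <- orient_and_scale(dm$coords, lg[, rna$anchor_gene])
    write_tsv_det(pt, file.path(cfg$out_dir, "pseudotime.tsv"))
    glob <- vapply(nmt$cpg, global_rate, 0)
    curves <- list()
    for (g in c("WT", "TetTKO")) {
      i <- nmt$truth$genotype == g
      cv <- loess_curve(pt$pseudotime[i], glob[i], span = cfg$pseudotime$span)
      curves[[g]] <- cbind(genotype = g, quantity = "global_cpg", cv)
    }
    write_tsv_det(do.call(rbind, curves),
                  file.path(cfg$out_dir, "methylation_curves.tsv"))
  })

  invisible(jsonlite::read_json(manifest_path))
}
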