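test_that("atlas generator is reproducible and respects composition", {
  spec <- atlas_spec(n_cell_types = 3, n_genes = 300, n_markers_per_type = 20,
                     stages = "E8.5", stage_composition = matrix(1 / 3, 1, 3),
                     seed = 9L)
  a1 <- simulate_atlas(spec, n_cells = 3000)
  a2 <- simulate_atlas(spec, n_cells = 3000)
  expect_identical(as.matrix(a1$counts$counts), as.matrix(a2$counts$counts))
  expect_identical(a1$annotation, a2$annotation)
  # equal proportions: per-type counts inside the binomial 99% envelope
  tab <- table(a1$annotation$cell_type)
  lo <- qbinom(0.005, 3000, 1 / 3); hi <- qbinom(0.995, 3000, 1 / 3)
  expect_true(all(tab >= lo & tab <= hi))
})

test_that("vanishing dispersion approaches the Poisson limit", {
  spec <- atlas_spec(n_cell_types = 2, n_genes = 200, n_markers_per_type = 5,
                     stages = "E8.5", stage_composition = matrix(0.5, 1, 2),
                     nb_dispersion = 1e-8, library_size_sdlog = 0, seed = 3L)
  a <- simulate_atlas(spec, n_cells = 500)
  one_type <- a$annotation$cell_type == a$annotation$cell_type[1]
  m <- as.matrix(a$counts$counts[one_type, ])
  mu <- colMeans(m); v <- apply(m, 2, var)
  ratio <- v[mu > 5] / mu[mu > 5]
  expect_lt(abs(median(ratio) - 1), 0.15)
})

test_that("marker capacity overflow is rejected", {
  expect_error(atlas_spec(n_cell_types = 5, n_genes = 50,
                          n_markers_per_type = 20),
               "n_markers_per_type")
})

test_that("planted proportion shifts follow the closed-form renormalization", {
  spec <- atlas_spec(seed = 15L)
  pert <- perturbation_spec(fold_changes = c(Erythroid = 0.25))
  comp <- perturbed_composition(spec, pert, "E8.5")
  base <- spec$stage_composition["E8.5", ]
  expect_equal(sum(comp), 1)
  expect_equal(comp[["Erythroid"]],
               0.25 * base[["Erythroid"]] /
                 (1 - 0.75 * base[["Erythroid"]]))
  q <- simulate_query_embryos(spec, pert, n_embryos = 5,
                              n_cells_per_embryo = 400, seed = 16L)
  frac <- mean(q$annotation$cell_type == "Erythroid")
  expect_lt(abs(frac - comp[["Erythroid"]]), 0.02)
})

test_that("delay shift reuses the earlier stage's composition", {
  spec <- atlas_spec(seed = 4L)
  delayed <- perturbed_composition(spec, perturbation_spec(delay_shift = 1),
                                   "E8.5")
  expect_equal(unname(delayed), unname(spec$stage_composition["E8.0", ]))
})

test_that("unknown cell types and genes in perturbations are rejected", {
  spec <- atlas_spec(seed = 4L)
  expect_error(perturbed_composition(
    spec, perturbation_spec(fold_changes = c(Notochord = 2)), "E8.5"),
    "unknown cell type")
  expect_error(simulate_query_embryos(
    spec, perturbation_spec(dysregulated_genes = data.frame(
      gene = "nope", log2fc = 2, cell_type = "all")), n_embryos = 1,
    n_cells_per_embryo = 10, seed = 1),
    "not in gene set")
})

test_that("dysregulated genes shift only their affected cell types", {
  spec <- atlas_spec(seed = 21L, batch_sdlog = 0)
  g <- "gene_0500"
  pert <- perturbation_spec(dysregulated_genes = data.frame(
    gene = g, log2fc = 3, cell_type = "Erythroid"))
  q0 <- simulate_query_embryos(spec, perturbation_spec(), n_embryos = 6,
                               n_cells_per_embryo = 400, seed = 22L,
                               batch = FALSE)
  q1 <- simulate_query_embryos(spec, pert, n_embryos = 6,
                               n_cells_per_embryo = 400, seed = 22L,
                               batch = FALSE)
  mean_in <- function(q, type) {
    i <- q$annotation$cell_type == type
    mean(q$counts$counts[i, g])
  }
  expect_gt(mean_in(q1, "Erythroid") / mean_in(q0, "Erythroid"), 4)
  expect_lt(abs(log2(mean_in(q1, "Epiblast") / mean_in(q0, "Epiblast"))), 0.5)
})

test_that("synthetic bisulfite rates hit their planted endpoints", {
  espec <- epigenome_spec(global_demethylation_slope = 0, seed = 31L,
                          cpg_coverage = 0.5)
  fs <- simulate_feature_set(espec, c(erythroid_enhancers = 20), width = 2000)
  res <- simulate_nmt_cells(espec, fs, time = c(1, 1, 0, 0),
                            genotype = c("WT", "TetTKO", "WT", "TetTKO"))
  frm <- feature_rate_matrix(res$cpg, fs)
  mean_rate <- function(cell) {
    x <- frm[frm$cell_id == cell & frm$class == "erythroid_enhancers", ]
    sum(x$n_meth) / sum(x$n_total)
  }
  ids <- res$truth$cell_id
  expect_lt(abs(mean_rate(ids[1]) - 0.2), 0.05)  # WT endpoint
  expect_lt(abs(mean_rate(ids[2]) - 0.8), 0.05)  # TKO stays at baseline
  # at time 0 the genotypes are indistinguishable by construction
  expect_equal(nmt_true_rate(espec, "erythroid_enhancers", 0, "WT"),
               nmt_true_rate(espec, "erythroid_enhancers", 0, "TetTKO"))
})

test_that("bisulfite generator validates latent time and reproduces itself", {
  espec <- epigenome_spec(seed = 41L)
  fs <- simulate_feature_set(espec, c(promoters = 3))
  expect_error(simulate_nmt_cells(espec, fs, time = c(0.5, 1.2)),
               "latent time")
  r1 <- simulate_nmt_cells(espec, fs, time = c(0.2, 0.8))
  r2 <- simulate_nmt_cells(espec, fs, time = c(0.2, 0.8))
  expect_identical(lapply(r1$cpg, function(m) as.data.frame(m$calls)),
                   lapply(r2$cpg, function(m) as.data.frame(m$calls)))
})
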