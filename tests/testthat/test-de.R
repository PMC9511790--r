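test_that("pseudobulk sums member cells and drops thin samples", {
  m <- rbind(c(1, 0), c(2, 1), c(3, 2), c(10, 5))
  dimnames(m) <- list(sprintf("c%d", 1:4), c("gA", "gB"))
  ann <- data.frame(cell_id = rownames(m),
                    embryo_id = c("e1", "e1", "e1", "e2"),
                    genotype = c("WT", "WT", "WT", "KO"),
                    cell_type = "T")
  pb <- make_pseudobulk(count_matrix(m), ann, "T", min_cells_per_sample = 1)
  expect_equal(unname(pb$counts["gA", ]), c(6, 10))
  expect_equal(unname(pb$n_cells), c(3, 1))
  pb2 <- make_pseudobulk(count_matrix(m), ann, "T", min_cells_per_sample = 2)
  expect_equal(colnames(pb2$counts), "e1")
})

test_that("median-of-ratios factors have the stated scaling properties", {
  m <- matrix(rpois(100 * 2, 60), 100, 2)
  m <- cbind(m[, 1], m[, 1])                 # two identical samples
  expect_equal(unname(median_of_ratios(m)), c(1, 1))
  m2 <- cbind(m[, 1], m[, 1] * 2)            # doubled sample
  f <- median_of_ratios(m2)
  expect_equal(f[2] / f[1], 2)
})

test_that("BH adjustment matches a brute-force step-up oracle exactly", {
  set.seed(55)
  for (n in c(1, 10, 313, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), bh_stepup_oracle(p))
  }
  # and within a DE result: adjusted p is monotone in the raw p ranking
  pb <- simulate_pseudobulk(seed = 56)
  res <- nb_test(pb)
  expect_equal(res$padj, bh_stepup_oracle(res$pvalue))
  o <- order(res$pvalue)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
})

test_that("flat genes are not called and all-zero genes leave the family", {
  pb <- simulate_pseudobulk(n_genes = 100, seed = 57)
  pb$counts[1, ] <- 44                      # identical counts in all samples
  pb$counts[2, ] <- 0                       # never observed
  pb$factor <- median_of_ratios(pb$counts)
  res <- nb_test(pb)
  expect_false("g0002" %in% res$gene)
  r1 <- res[res$gene == "g0001", ]
  expect_lt(abs(r1$log2fc), 0.2)
  expect_false(r1$significant)
  expect_equal(r1$direction, 0)
})

test_that("fold changes are scale-invariant and order-invariant", {
  pb <- simulate_pseudobulk(n_genes = 200, lfc_genes = 1:20, lfc = 2,
                            seed = 58)
  res <- nb_test(pb)
  pb2 <- pb
  pb2$counts <- pb$counts * 2L
  pb2$factor <- pb$factor * 2
  res2 <- nb_test(pb2)
  expect_lt(max(abs(res$log2fc - res2$log2fc)), 1e-6)
  perm_s <- sample(ncol(pb$counts)); perm_g <- sample(nrow(pb$counts))
  pb3 <- structure(list(counts = pb$counts[perm_g, perm_s],
                        factor = pb$factor[perm_s],
                        group = pb$group[perm_s],
                        n_cells = pb$n_cells[perm_s]),
                   class = "PseudobulkMatrix")
  res3 <- nb_test(pb3, contrast = c("WT", "KO"))
  res3 <- res3[match(res$gene, res3$gene), ]
  expect_equal(res$log2fc, res3$log2fc, tolerance = 1e-8)
  expect_equal(res$pvalue, res3$pvalue, tolerance = 1e-8)
})

test_that("both test flavours are calibrated and powered on NB data", {
  null <- nb_test(simulate_pseudobulk(n_genes = 800, seed = 59))
  expect_lte(mean(null$significant), 0.03)
  planted <- simulate_pseudobulk(n_genes = 800, lfc_genes = 1:50, lfc = 2,
                                 seed = 60)
  for (method in c("ql", "lrt")) {
    res <- nb_test(planted, method = method)
    expect_gte(mean(res$significant[match(sprintf("g%04d", 1:50),
                                          res$gene)]), 0.8)
    expect_lte(mean(res$significant[-match(sprintf("g%04d", 1:50),
                                           res$gene)]), 0.03)
  }
})

test_that("restricting the analysis restricts the BH family", {
  pb <- simulate_pseudobulk(n_genes = 300, lfc_genes = 1:30, lfc = 2,
                            seed = 61)
  keep <- sprintf("g%04d", 1:100)
  res <- nb_test(pb, genes = keep)
  expect_true(all(res$gene %in% keep))
  expect_equal(res$padj, bh_stepup_oracle(res$pvalue))
})

test_that("the 75% pairwise rule is strict and allows shared markers", {
  # C = 5: a gene upregulated in A and E is DE in only 3/4 of A's
  # comparisons (0.75, not strictly more) and must not be an A marker;
  # a gene upregulated only in A (4/4) must be.
  fx <- marker_fixture(5, list(gAE = c("A", "E"), gA = "A"))
  mk <- find_markers(fx$cm, fx$ann)
  expect_true("gA" %in% mk$A)
  expect_false("gAE" %in% mk$A)
  expect_false("gAE" %in% mk$E)
  n_de <- attr(mk, "n_de")
  expect_equal(unname(n_de["gAE", c("A", "E")]), c(3L, 3L))
  expect_equal(unname(n_de["gA", "A"]), 4L)
  # C = 6: 4/5 comparisons exceed 75%, so a gene can mark two cell types
  fx6 <- marker_fixture(6, list(gAB = c("A", "B")))
  mk6 <- find_markers(fx6$cm, fx6$ann)
  expect_true("gAB" %in% mk6$A)
  expect_true("gAB" %in% mk6$B)
  expect_error(find_markers(fx$cm, fx$ann[fx$ann$cell_type %in%
                                            c("A", "B"), ]),
               "at least 3")
})

test_that("DE genes cross-tabulate by marker identity with multiplicity", {
  de <- list(Erythroid = data.frame(
    gene = c("g1", "g2", "g3"), log2fc = c(2, -3, 1.5),
    dispersion = 0.1, stat = 1, pvalue = 0.001, padj = 0.005,
    significant = c(TRUE, TRUE, FALSE), direction = c(1, -1, 0)))
  markers <- list(ery = c("g1", "g9"), neural = c("g1", "g2"))
  tab <- de_by_marker_identity(de, markers)
  expect_equal(tab$n_genes[tab$direction == "up" & tab$marker_type == "ery"], 1)
  expect_equal(tab$n_genes[tab$direction == "up" &
                             tab$marker_type == "neural"], 1)
  expect_equal(tab$n_genes[tab$direction == "down" &
                             tab$marker_type == "neural"], 1)
  # empty DE set: all counts zero
  de0 <- list(T = de$Erythroid[0, ])
  expect_true(all(de_by_marker_identity(de0, markers)$n_genes == 0))
})

test_that("gene-set summaries report untested genes separately", {
  de <- list(T1 = data.frame(
    gene = c("hoxA", "hoxB"), log2fc = c(1.5, 0.2), dispersion = 0.1,
    stat = 1, pvalue = c(1e-4, 0.6), padj = c(1e-3, 0.7),
    significant = c(TRUE, FALSE), direction = c(1, 0)))
  sm <- gene_set_summary(de, list(hox = c("hoxA", "hoxB", "hoxZ")))
  expect_equal(sm$set_counts$n_up, 1)
  expect_equal(sm$set_counts$n_down, 0)
  expect_equal(sm$set_counts$n_untested, 1)
  expect_equal(sm$untested$hox, "hoxZ")
  expect_equal(nrow(sm$log2fc), 3)
  expect_true(is.na(sm$log2fc$T1[sm$log2fc$gene == "hoxZ"]))
})
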