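test_that("highly variable gene selection recovers planted variable genes", {
  set.seed(8)
  n_cells <- 300
  flat <- matrix(rnorm(n_cells * 2000, 2, 0.1), n_cells, 2000)
  planted <- matrix(rnorm(n_cells * 100, 2, 1.5), n_cells, 100)
  x <- cbind(planted, flat)
  colnames(x) <- c(sprintf("hv%03d", 1:100), sprintf("flat%04d", 1:2000))
  top <- select_hvgs(x, 100)
  expect_gte(sum(grepl("^hv", top)), 95)
})

test_that("constant genes are never selected and the full set is identity", {
  set.seed(9)
  x <- cbind(matrix(rnorm(200 * 9), 200, 9), 1)
  colnames(x) <- c(sprintf("g%d", 1:9), "const")
  expect_false("const" %in% select_hvgs(x, 5))
  expect_setequal(select_hvgs(x, 10), colnames(x))
  expect_warning(select_hvgs(x, 20), "n_hvgs")
})

test_that("joint PCA detects rank, is deterministic and orders variance", {
  set.seed(10)
  basis <- matrix(rnorm(3 * 40), 3, 40)
  scores <- matrix(rnorm(120 * 3), 120, 3) %*% diag(c(5, 3, 1))
  x <- scores %*% basis
  rownames(x) <- sprintf("c%03d", 1:120)
  colnames(x) <- sprintf("g%02d", 1:40)
  ref <- x[1:60, ]; qry <- x[61:120, ]
  qry[1, ] <- ref[1, ]                       # duplicated cell across batches
  p <- joint_pca(ref, qry, colnames(x), n_pcs = 10)
  expect_lt(sum(p$var_explained[4:10]), 1e-10)
  expect_equal(p$coords[1, ], p$coords[61, ])
  expect_true(all(diff(p$var_explained) <= 1e-12))
  p2 <- joint_pca(ref, qry, colnames(x), n_pcs = 10)
  expect_identical(p$coords, p2$coords)      # sign convention is fixed
})

test_that("MNN correction removes a constant batch shift", {
  set.seed(11)
  ref <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(sprintf("r%03d", 1:200), NULL))
  v <- rnorm(10); v <- v / sqrt(sum(v^2)) * 0.5
  qry <- sweep(ref, 2, -v)                   # query = reference + v
  rownames(qry) <- sprintf("q%03d", 1:200)
  batch <- factor(rep(c("reference", "query"), each = 200),
                  levels = c("reference", "query"))
  res <- mnn_correct(rbind(ref, qry), batch, mnn_k = 20, mnn_sigma = 0.1)
  resid <- res$coords[batch == "query", ] - ref
  expect_lt(max(sqrt(rowSums(resid^2))), 0.05 * sqrt(sum(v^2)))
  expect_equal(res$coords[batch == "reference", ], ref)
  # identical batches: corrections vanish
  res0 <- mnn_correct(rbind(ref, `rownames<-`(ref, rownames(qry))), batch,
                      20, 0.1)
  expect_lt(max(abs(res0$coords[batch == "query", ] - ref)), 1e-10)
})

test_that("mutual pairs mostly connect cells of the same type", {
  fx <- small_map_fixture()
  res <- suppressWarnings(map_to_reference(
    fx$atlas$counts, fx$query$counts, fx$atlas$annotation$cell_type,
    mapping_params(n_hvgs = 150, n_pcs = 20)))
  pca <- local({
    shared <- gene_ids(fx$atlas$counts)
    rl <- normalized_matrix(fx$atlas$counts)
    ql <- normalized_matrix(fx$query$counts)
    hv <- select_hvgs(rbind(rl, ql), 150)
    joint_pca(rl, ql, hv, 20)
  })
  pairs <- mnn_correct(pca$coords, pca$batch, 20, 0.1)$pairs
  t_ref <- fx$atlas$annotation$cell_type[
    match(pairs$reference, fx$atlas$annotation$cell_id)]
  t_qry <- fx$query$annotation$cell_type[
    match(pairs$query, fx$query$annotation$cell_id)]
  expect_gte(mean(t_ref == t_qry), 0.8)
})

test_that("majority voting assigns by neighbour counts with stated tie-breaks", {
  # 30 reference cells on a line; query at origin sees 20 A's and 10 B's
  ref <- cbind(c(seq(0.1, 2, length.out = 20), seq(2.5, 4, length.out = 10)))
  rownames(ref) <- sprintf("r%02d", 1:30)
  qry <- cbind(0); rownames(qry) <- "q1"
  coords <- rbind(ref, qry)
  batch <- factor(rep(c("reference", "query"), c(30, 1)),
                  levels = c("reference", "query"))
  labels <- rep(c("A", "B"), c(20, 10))
  res <- transfer_labels(coords, batch, labels, k_neighbors = 30)
  expect_equal(res$assignment$cell_type, "A")
  expect_equal(res$assignment$confidence, 20 / 30)
  # 15/15 tie: type with smaller summed distance wins
  labels2 <- rep(c("A", "B"), c(15, 15))   # A's sit nearer the query
  res2 <- transfer_labels(coords, batch, labels2, k_neighbors = 30)
  expect_equal(res2$assignment$cell_type, "A")
  expect_error(transfer_labels(coords, batch, labels, k_neighbors = 31),
               "exceeds")
})

test_that("voting with k = 1 equals exhaustive nearest-neighbour search", {
  fx <- small_map_fixture()
  res <- suppressWarnings(map_to_reference(
    fx$atlas$counts, fx$query$counts, fx$atlas$annotation$cell_type,
    mapping_params(n_hvgs = 150, n_pcs = 20, k_neighbors = 1)))
  coords <- res$coords
  ref_i <- res$batch == "reference"
  d2 <- scembryo:::cross_dist2(coords[!ref_i, , drop = FALSE],
                               coords[ref_i, , drop = FALSE])
  oracle <- fx$atlas$annotation$cell_type[apply(d2, 1, which.min)]
  expect_identical(res$assignment$cell_type, oracle)
})

test_that("assignments are invariant to cell order", {
  fx <- small_map_fixture()
  qcm <- fx$query$counts
  perm <- sample(nrow(qcm$counts))
  shuffled <- subset_cells(qcm, cells = perm)
  p <- mapping_params(n_hvgs = 150, n_pcs = 20)
  r1 <- suppressWarnings(map_to_reference(fx$atlas$counts, qcm,
                                          fx$atlas$annotation$cell_type, p))
  r2 <- suppressWarnings(map_to_reference(fx$atlas$counts, shuffled,
                                          fx$atlas$annotation$cell_type, p))
  a1 <- r1$assignment[match(r2$assignment$cell_id, r1$assignment$cell_id), ]
  expect_identical(a1$cell_type, r2$assignment$cell_type)
})

test_that("neighbour highlighting flags exactly the voting neighbours", {
  ref <- cbind(seq_len(40)); rownames(ref) <- sprintf("r%02d", 1:40)
  qry <- cbind(c(0, 100)); rownames(qry) <- c("qA", "qB")
  coords <- rbind(ref, qry)
  batch <- factor(rep(c("reference", "query"), c(40, 2)),
                  levels = c("reference", "query"))
  res <- transfer_labels(coords, batch, rep("T", 40), k_neighbors = 30)
  hl <- highlight_neighbors(res, rownames(ref),
                            list(low = "qA", high = "qB"))
  expect_equal(sum(hl$low), 30)
  expect_equal(sum(hl$high), 30)
  expect_true(all(hl$low[1:30]))           # qA's neighbours are the nearest 30
  expect_false(hl$low[40])
  expect_true(all(hl$high[11:40]))         # computed independently for qB
})
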