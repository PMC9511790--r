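test_that("feature aggregation binarizes sites and skips empty features", {
  calls <- meth_call_set(data.frame(chrom = "chr1",
                                    pos = c(150, 160, 170, 900),
                                    meth = c(3, 0, 1, 2),
                                    unmeth = c(0, 2, 0, 0)), "CpG")
  fs <- feature_set("chr1", c(100, 500), c(200, 600),
                    name = c("f1", "f2"), class_label = "enh")
  agg <- aggregate_features(calls, fs)
  expect_equal(nrow(agg), 1)                     # f2 has no coverage: missing
  expect_equal(agg$feature, "f1")
  expect_equal(agg$n_total, 3)
  expect_equal(agg$n_meth, 2)                    # binarized {1, 0, 1}
  expect_equal(agg$rate, 2 / 3)
})

test_that("overlapping features each receive shared sites", {
  calls <- meth_call_set(data.frame(chrom = "chr1", pos = 150,
                                    meth = 1, unmeth = 0), "CpG")
  fs <- feature_set("chr1", c(100, 120), c(200, 220),
                    name = c("f1", "f2"), class_label = "enh")
  agg <- aggregate_features(calls, fs)
  expect_equal(sort(agg$feature), c("f1", "f2"))
  expect_equal(agg$n_total, c(1, 1))
})

test_that("aggregation agrees exactly with a brute-force interval scan", {
  for (seed in c(4, 91)) {
    fx <- random_agg_fixture(seed)
    agg <- aggregate_features(fx$calls, fx$fs)
    oracle <- aggregate_oracle(fx$calls, fx$fs)
    agg <- agg[order(agg$feature), ]
    oracle <- oracle[order(oracle$feature), ]
    expect_equal(agg$feature, oracle$feature)
    expect_equal(agg$n_total, oracle$n_total)
    expect_equal(agg$n_meth, oracle$n_meth)
    expect_true(all(agg$rate >= 0 & agg$rate <= 1))
  }
})

test_that("totals are conserved when features tile the covered region", {
  fx <- random_agg_fixture(7)
  tiles <- feature_set("chr1", seq(0, 49000, by = 1000),
                       seq(1000, 50000, by = 1000), class_label = "tile")
  agg <- aggregate_features(fx$calls, tiles)
  expect_equal(sum(agg$n_total), nrow(fx$calls$calls))
  # non-overlapping features never exceed the number of covered sites
  agg2 <- aggregate_features(fx$calls, fx$fs[1:10])
  expect_lte(sum(agg2$n_total), nrow(fx$calls$calls))
})

test_that("aggregation of an empty call set is empty, and global rates work", {
  empty <- meth_call_set(data.frame(chrom = character(0), pos = integer(0),
                                    meth = numeric(0), unmeth = numeric(0)),
                         "GpC")
  fs <- feature_set("chr1", 0, 100)
  expect_equal(nrow(aggregate_features(empty, fs)), 0)
  expect_error(global_rate(empty), "no covered sites")
  full <- meth_call_set(data.frame(chrom = "chr1", pos = c(1, 5),
                                   meth = c(2, 1), unmeth = c(0, 0)), "CpG")
  expect_equal(global_rate(full), 1)
  half <- meth_call_set(data.frame(chrom = "chr1", pos = c(1, 5),
                                   meth = c(1, 0), unmeth = c(0, 1)), "CpG")
  expect_equal(global_rate(half), 0.5)
})

test_that("profiles use the stated window layout", {
  pp <- profile_params()
  expect_error(profile_params(50, 1975), "divisible")
  calls <- list(meth_call_set(data.frame(chrom = "chr1",
                                         pos = c(3001, 4990),
                                         meth = c(1, 0), unmeth = c(0, 1)),
                              "CpG"))
  fs <- feature_set("chr1", 4500, 5500)        # centre at 5000 (0-based)
  pr <- meth_profile(calls, fs, pp)
  expect_equal(nrow(pr), 2 * 2000 / 50)        # 80 windows
  expect_equal(pr$offset, seq(-2000, 1950, by = 50))
  expect_equal(pr$mean[pr$offset == -2000], 1) # site at offset -2000
  expect_equal(pr$mean[pr$offset == -50], 0)   # site at offset -11
  expect_true(all(is.na(pr$mean[!pr$offset %in% c(-2000, -50)])))
  expect_error(meth_profile(list(), fs, pp), "empty")
})

test_that("profiles of a symmetric signal are symmetric about the centre", {
  espec <- epigenome_spec(global_demethylation_slope = 0, seed = 13L,
                          cpg_coverage = 0.6)
  fs <- simulate_feature_set(espec, c(erythroid_enhancers = 15), width = 1000)
  res <- simulate_nmt_cells(espec, fs, time = rep(1, 30), genotype = "WT")
  pr <- meth_profile(res$cpg, fs)
  half <- nrow(pr) / 2
  left <- rev(pr$mean[1:half]); right <- pr$mean[(half + 1):nrow(pr)]
  # compare mirrored window pairs (right window k pairs with left window k+1)
  expect_lt(mean(abs(left[-1] - right[-length(right)])), 0.08)
})

test_that("the planted enhancer dip appears in WT and not in TKO profiles", {
  fx <- nmt_fixture()
  ery <- fx$fs[S4Vectors::mcols(fx$fs)$class == "erythroid_enhancers"]
  dip <- function(g) {
    pr <- meth_profile(fx$ery$nmt$cpg[fx$ery$genotype == g], ery)
    centre <- mean(pr$mean[pr$offset >= -250 & pr$offset < 200])
    edge <- mean(pr$mean[abs(pr$offset) >= 1600])
    edge - centre
  }
  expect_gte(dip("WT"), 0.2)
  expect_lt(abs(dip("TetTKO")), 0.05)
})

test_that("group comparison reports medians, tests and planted effects", {
  # identical groups: difference 0, p = 1
  frm <- data.frame(cell_id = rep(sprintf("c%d", 1:10), each = 2),
                    feature = rep(c("f1", "f2"), 10),
                    class = "enh", n_meth = 1, n_total = 2,
                    rate = rep(seq(0.1, 1, by = 0.1), each = 2))
  cmp <- compare_groups(frm, list(g1 = sprintf("c%d", 1:10),
                                  g2 = sprintf("c%d", 1:10)))
  expect_equal(cmp$diff_median, 0)
  expect_gt(cmp$pvalue, 0.99)
  # planted 0.6 difference at erythroid enhancers; promoters quiet
  fx <- nmt_fixture()
  frm2 <- feature_rate_matrix(fx$ery$nmt$cpg, fx$fs)
  cmp2 <- compare_groups(
    frm2,
    list(WT = fx$ery$nmt$truth$cell_id[fx$ery$genotype == "WT"],
         TetTKO = fx$ery$nmt$truth$cell_id[fx$ery$genotype == "TetTKO"]))
  ery <- cmp2[cmp2$class == "erythroid_enhancers", ]
  expect_lt(abs(abs(ery$diff_median) - 0.6), 0.1)
  expect_lt(ery$padj, 0.01)
  expect_lt(abs(cmp2$diff_median[cmp2$class == "promoters"]), 0.05)
})

test_that("accessibility shares the code path and GpC-free input is empty", {
  fx <- nmt_fixture()
  gpc <- fx$traj$nmt$gpc[[1]]
  expect_identical(gpc$context, "GpC")
  agg <- aggregate_features(gpc, fx$fs)
  expect_true(all(agg$rate >= 0 & agg$rate <= 1))
  none <- meth_call_set(data.frame(chrom = "chrZ", pos = 5,
                                   meth = 1, unmeth = 0), "GpC")
  expect_equal(nrow(aggregate_features(none, fx$fs)), 0)
})
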