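#' Metaprofile window parameters
#'
#' @param window_size running-average window in bp (default 50).
#' @param flank bp profiled up- and downstream of each feature centre
#'   (default 2000); must be divisible by `window_size`.
#' @return an object of class `ProfileParams`.
#' @export
profile_params <- function(window_size = 50, flank = 2000) {
  if (flank %% window_size != 0)
    abort("flank must be divisible by window_size")
  structure(list(window_size = window_size, flank = flank),
            class = "ProfileParams")
}

#' Aggregate one cell's calls over genomic features
#'
#' Per feature: `n_total` is the number of covered sites whose position
#' falls inside the feature, `n_meth` the number of those with binarized
#' site rate 1 (see [binary_site_rates()]), and `rate = n_meth / n_total`
#' follows the binomial model (trials = observed sites, successes =
#' methylated sites). A site inside several overlapping features
#' contributes to each of them. Features with no covered sites are absent
#' from the output (missing, never zero).
#'
#' @param mcs a `MethCallSet`; @param fs a `GRanges` feature set.
#' @return data.frame: cell_id, feature, class, n_meth, n_total, rate.
#' @export
aggregate_features <- function(mcs, fs) {
  dt <- mcs$calls
  empty <- data.frame(cell_id = character(0), feature = character(0),
                      class = character(0), n_meth = numeric(0),
                      n_total = numeric(0), rate = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(dt)) return(empty)
  sites <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  hits <- GenomicRanges::findOverlaps(sites, fs)
  if (!length(hits)) return(empty)
  b <- binary_site_rates(mcs)[S4Vectors::queryHits(hits)]
  f <- S4Vectors::subjectHits(hits)
  n_total <- tapply(b, f, length)
  n_meth <- tapply(b, f, sum)
  fi <- as.integer(names(n_total))
  data.frame(cell_id = mcs$cell_id,
             feature = S4Vectors::mcols(fs)$name[fi],
             class = S4Vectors::mcols(fs)$class[fi],
             n_meth = as.numeric(n_meth),
             n_total = as.numeric(n_total),
             rate = as.numeric(n_meth) / as.numeric(n_total),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Feature-rate matrix over many cells (long format)
#'
#' @param calls list of `MethCallSet` (one per cell).
#' @param fs a `GRanges` feature set.
#' @return long data.frame as in [aggregate_features()], one block per cell;
#'   (cell, feature) pairs with zero coverage are simply absent.
#' @export
feature_rate_matrix <- function(calls, fs) {
  do.call(rbind, lapply(calls, aggregate_features, fs = fs))
}

#' Global methylation (or accessibility) rate of one cell
#'
#' Mean of binarized site rates over all covered sites.
#' @param mcs a `MethCallSet` with at least one site.
#' @return rate in [0, 1].
#' @export
global_rate <- function(mcs) {
  if (!nrow(mcs$calls)) abort("cell '%s' has no covered sites", mcs$cell_id)
  mean(binary_site_rates(mcs))
}

#' Feature-centred methylation/accessibility metaprofile
#'
#' For each cell, covered sites within `flank` bp of any feature centre
#' (centre = midpoint, windows half-open `[c + o, c + o + w)` for offsets
#' `o = -flank, ..., flank - w`) are pooled across all features of the
#' class, and the per-window rate is the mean binarized site rate. Group
#' mean and standard deviation are then taken across cells; cells with no
#' sites in a window are excluded from that window's statistics.
#'
#' @param calls list of `MethCallSet` (the cell group; must be non-empty).
#' @param fs features of one class (a `GRanges`).
#' @param params a [profile_params()].
#' @return data.frame: offset (window start relative to centre), mean, sd,
#'   n_cells.
#' @export
meth_profile <- function(calls, fs, params = profile_params()) {
  if (!length(calls)) abort("empty cell group")
  w <- params$window_size; flank <- params$flank
  offsets <- seq(-flank, flank - w, by = w)
  # 0-based centre of the original half-open interval
  centre <- floor((GenomicRanges::start(fs) - 1 + GenomicRanges::end(fs)) / 2)
  centres <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(fs),
    IRanges::IRanges(centre - flank + 1, centre + flank))
  per_cell <- lapply(calls, function(mcs) {
    dt <- mcs$calls
    if (!nrow(dt)) return(NULL)
    sites <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
    hits <- GenomicRanges::findOverlaps(sites, centres)
    if (!length(hits)) return(NULL)
    b <- binary_site_rates(mcs)[S4Vectors::queryHits(hits)]
    d <- (dt$pos[S4Vectors::queryHits(hits)] - 1) -
      centre[S4Vectors::subjectHits(hits)]        # 0-based offset from centre
    bin <- floor(d / w) * w
    rate <- tapply(b, bin, mean)
    data.frame(offset = as.numeric(names(rate)), rate = as.numeric(rate))
  })
  per_cell <- per_cell[!vapply(per_cell, is.null, TRUE)]
  stats_by <- lapply(offsets, function(o) {
    vals <- unlist(lapply(per_cell, function(x) x$rate[x$offset == o]))
    c(mean = if (length(vals)) mean(vals) else NA_real_,
      sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
      n = length(vals))
  })
  out <- do.call(rbind, stats_by)
  data.frame(offset = offsets, mean = out[, "mean"], sd = out[, "sd"],
             n_cells = as.integer(out[, "n"]), row.names = NULL)
}

#' Compare feature-class rates between two cell groups
#'
#' Per feature class: each cell's mean rate over the class's covered
#' features is computed; the report gives group medians, their difference,
#' a Wilcoxon rank-sum p-value and BH adjustment across classes. Effect
#' sizes are always reported; the test is skipped (NA) when either group
#' has fewer than 3 cells with coverage.
#'
#' @param frm long feature-rate data.frame (see [feature_rate_matrix()]).
#' @param groups named list of two cell-id vectors, e.g.
#'   `list(WT = ..., TetTKO = ...)`.
#' @return data.frame: class, median per group, diff_median (group1 -
#'   group2), n per group, pvalue, padj.
#' @export
compare_groups <- function(frm, groups) {
  if (length(groups) != 2 || is.null(names(groups)))
    abort("groups must be a named list of two cell-id vectors")
  g1 <- names(groups)[1]; g2 <- names(groups)[2]
  cell_means <- stats::aggregate(rate ~ cell_id + class, data = frm, FUN = mean)
  classes <- sort(unique(frm$class))
  rows <- lapply(classes, function(cl) {
    x <- cell_means[cell_means$class == cl, ]
    v1 <- x$rate[x$cell_id %in% groups[[g1]]]
    v2 <- x$rate[x$cell_id %in% groups[[g2]]]
    p <- if (length(v1) >= 3 && length(v2) >= 3)
      suppressWarnings(stats::wilcox.test(v1, v2)$p.value) else NA_real_
    out <- data.frame(class = cl,
                      m1 = stats::median(v1), m2 = stats::median(v2),
                      diff_median = stats::median(v1) - stats::median(v2),
                      n1 = length(v1), n2 = length(v2),
                      pvalue = p, stringsAsFactors = FALSE)
    names(out)[2:3] <- paste0("median_", c(g1, g2))
    names(out)[5:6] <- paste0("n_", c(g1, g2))
    out
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out
}
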