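#' Per-platform quality-control thresholds
#'
#' Droplet (10x-style 3') cells require at least 1500 UMIs with at most 30%
#' mitochondrial and 35% ribosomal reads; plate (Smart-seq2-style) cells,
#' which are sequenced deeper, require at least 4000 reads with at most 10%
#' mitochondrial and 20% ribosomal reads. Bisulfite cells require at least
#' 5000 covered CpGs with a global methylation of at least 50%, and at least
#' 10000 covered GpCs with global accessibility between 10% and 40%. All
#' comparisons are inclusive.
#'
#' @param min_counts,max_mito_pct,max_ribo_pct named 2-vectors
#'   (`droplet`, `plate`) of RNA thresholds.
#' @param meth_min_sites,acc_min_sites minimum covered sites per context.
#' @param meth_global_min minimum global CpG methylation percentage.
#' @param acc_global_range allowed global GpC accessibility range (percent).
#' @return an object of class `QCParams`.
#' @export
qc_params <- function(min_counts = c(droplet = 1500, plate = 4000),
                      max_mito_pct = c(droplet = 30, plate = 10),
                      max_ribo_pct = c(droplet = 35, plate = 20),
                      meth_min_sites = 5000,
                      acc_min_sites = 10000,
                      meth_global_min = 50,
                      acc_global_range = c(10, 40)) {
  assert_in_range(c(max_mito_pct, max_ribo_pct, meth_global_min,
                    acc_global_range), 0, 100, "QC percentages")
  if (any(min_counts <= 0)) abort("min_counts must be positive")
  structure(list(min_counts = min_counts, max_mito_pct = max_mito_pct,
                 max_ribo_pct = max_ribo_pct,
                 meth_min_sites = meth_min_sites,
                 acc_min_sites = acc_min_sites,
                 meth_global_min = meth_global_min,
                 acc_global_range = acc_global_range),
            class = "QCParams")
}

#' RNA cell quality control
#'
#' A cell passes iff its total count is at least the platform minimum AND its
#' mitochondrial and ribosomal percentages are at most the platform maxima
#' (inclusive comparisons throughout).
#'
#' @param cm a `CountMatrix`.
#' @param mito_genes,ribo_genes character vectors of gene ids (subsets of
#'   `gene_ids(cm)`); an empty mitochondrial set defines mito% as 0, with a
#'   warning.
#' @param params a [qc_params()].
#' @param platform `"droplet"` or `"plate"`.
#' @return data.frame: cell_id, total, mito_pct, ribo_pct, pass.
#' @export
qc_rna <- function(cm, mito_genes = character(0), ribo_genes = character(0),
                   params = qc_params(), platform = c("droplet", "plate")) {
  platform <- match.arg(platform)
  for (gs in list(mito_genes, ribo_genes)) {
    bad <- setdiff(gs, gene_ids(cm))
    if (length(bad)) abort("QC gene set contains unknown gene(s): %s", bad[1])
  }
  if (!length(mito_genes))
    warn("empty mitochondrial gene set; mito%% defined as 0")
  total <- Matrix::rowSums(cm$counts)
  pct_of <- function(genes) {
    if (!length(genes)) return(rep(0, nrow(cm$counts)))
    sub <- Matrix::rowSums(cm$counts[, genes, drop = FALSE])
    ifelse(total > 0, 100 * sub / total, 0)
  }
  mito_pct <- pct_of(mito_genes)
  ribo_pct <- pct_of(ribo_genes)
  pass <- total >= params$min_counts[[platform]] &
    mito_pct <= params$max_mito_pct[[platform]] &
    ribo_pct <= params$max_ribo_pct[[platform]]
  data.frame(cell_id = cell_ids(cm), total = as.numeric(total),
             mito_pct = mito_pct, ribo_pct = ribo_pct, pass = pass,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-site binarized methylation rates of a call set
#'
#' A site's binary rate is `meth / (meth + unmeth)` thresholded at 0.5, with
#' exactly 0.5 counted as methylated.
#' @param mcs a `MethCallSet`
#' @return 0/1 vector, one entry per site
#' @export
binary_site_rates <- function(mcs) {
  dt <- mcs$calls
  if (!nrow(dt)) return(numeric(0))
  as.numeric(dt$meth / (dt$meth + dt$unmeth) >= 0.5)
}

#' Bisulfite cell quality control
#'
#' Computes covered-site count and global rate (mean of binarized site
#' rates, see [binary_site_rates()]) and applies the context's gates: CpG
#' cells need `meth_min_sites` sites and a global rate of at least
#' `meth_global_min`%; GpC cells need `acc_min_sites` sites and a global rate
#' inside `acc_global_range`%.
#'
#' @param mcs a `MethCallSet`.
#' @param params a [qc_params()].
#' @return one-row data.frame: cell_id, context, n_sites, global_rate
#'   (percent), pass.
#' @export
qc_nmt <- function(mcs, params = qc_params()) {
  if (!inherits(mcs, "MethCallSet")) abort("qc_nmt expects a MethCallSet")
  n_sites <- nrow(mcs$calls)
  rate <- if (n_sites) 100 * mean(binary_site_rates(mcs)) else NA_real_
  pass <- if (mcs$context == "CpG") {
    n_sites >= params$meth_min_sites && !is.na(rate) &&
      rate >= params$meth_global_min
  } else {
    n_sites >= params$acc_min_sites && !is.na(rate) &&
      rate >= params$acc_global_range[1] && rate <= params$acc_global_range[2]
  }
  data.frame(cell_id = mcs$cell_id, context = mcs$context, n_sites = n_sites,
             global_rate = rate, pass = pass, stringsAsFactors = FALSE)
}

#' Cell size factors
#'
#' `method = "library"`: factors proportional to total counts. `method =
#' "pooled"`: the pool-and-deconvolve estimator of scran (counts are summed
#' over pools of cells and a least-squares system is solved for per-cell
#' factors), which is robust to differential expression between cells; for
#' fewer than 50 cells the library-size method is used instead. Factors are
#' rescaled to mean 1.
#'
#' @param cm a `CountMatrix` of QC-passing cells (at least 2; no zero-total
#'   cells).
#' @param method `"pooled"` or `"library"`.
#' @return list of class `NormalizationModel`: `size_factor` (named, mean 1)
#'   and `method`.
#' @export
size_factors <- function(cm, method = c("pooled", "library")) {
  method <- match.arg(method)
  total <- Matrix::rowSums(cm$counts)
  if (nrow(cm$counts) < 2) abort("need at least 2 cells")
  if (any(total == 0))
    abort("cell(s) with zero total counts: %s",
          cell_ids(cm)[which(total == 0)[1]])
  used <- method
  if (method == "pooled" && nrow(cm$counts) < 50) {
    used <- "library"
    warn("fewer than 50 cells; falling back to library-size factors")
  }
  sf <- if (used == "library") {
    as.numeric(total)
  } else {
    sizes <- unique(pmin(c(5L, 10L, 20L), nrow(cm$counts)))
    as.numeric(scran::calculateSumFactors(Matrix::t(cm$counts), sizes = sizes))
  }
  sf <- sf / mean(sf)
  structure(list(size_factor = stats::setNames(sf, cell_ids(cm)),
                 method = used),
            class = "NormalizationModel")
}

#' Size-factor-normalized, log1p-transformed expression
#'
#' @param cm a `CountMatrix`; @param norm a `NormalizationModel` (defaults to
#'   library-size factors).
#' @param log if `TRUE` (default) return `log1p(count / factor)`.
#' @return dense cells x genes matrix.
#' @export
normalized_matrix <- function(cm, norm = NULL, log = TRUE) {
  norm <- norm %||% size_factors(cm, "library")
  sf <- norm$size_factor[cell_ids(cm)]
  m <- as.matrix(cm$counts) / sf
  if (log) log1p(m) else m
}
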