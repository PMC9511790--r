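#' Construct a cell-by-gene count matrix
#'
#' The central RNA container of the package: a sparse, non-negative integer
#' matrix with cells as rows and genes as columns, plus optional human-readable
#' gene names aligned to the gene identifiers.
#'
#' @param counts matrix or sparse Matrix (cells x genes) of non-negative
#'   integer counts. Row names are cell identifiers, column names gene
#'   identifiers; both must be unique.
#' @param gene_names optional character vector of gene symbols aligned to the
#'   columns of `counts`; defaults to the gene identifiers.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `gene_names`.
#' @examples
#' m <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = c(3, 5), dims = c(2, 3),
#'                           dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(counts, gene_names = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    abort("counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must carry cell (row) and gene (column) identifiers")
  if (anyDuplicated(rownames(counts))) abort("duplicate cell identifiers")
  if (anyDuplicated(colnames(counts))) abort("duplicate gene identifiers")
  gene_names <- gene_names %||% colnames(counts)
  if (length(gene_names) != ncol(counts))
    abort("gene_names length (%d) does not match gene count (%d)",
          length(gene_names), ncol(counts))
  structure(list(counts = counts, gene_names = as.character(gene_names)),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Cell and gene identifiers of a CountMatrix
#' @param x a `CountMatrix`
#' @return character vector of identifiers
#' @export
cell_ids <- function(x) rownames(x$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$counts)

#' Subset a CountMatrix by cells and/or genes
#' @param x a `CountMatrix`
#' @param cells,genes index vectors (logical, integer, or identifier)
#' @return a `CountMatrix`
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  m <- x$counts
  gn <- x$gene_names
  if (!is.null(genes)) {
    gi <- if (is.character(genes)) match(genes, colnames(m)) else seq_len(ncol(m))[genes]
    if (anyNA(gi)) abort("unknown gene identifier(s)")
    m <- m[, gi, drop = FALSE]
    gn <- gn[gi]
  }
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  count_matrix(m, gn)
}

#' Construct a per-cell methylation call set
#'
#' Holds bisulfite calls for one cell and one cytosine context: for each
#' covered site, the number of reads supporting methylation and the number
#' supporting no methylation. Duplicate positions on the same chromosome are
#' merged by summing counts.
#'
#' @param calls data.frame with columns `chrom`, `pos` (1-based position),
#'   `meth` and `unmeth` (non-negative read counts, `meth + unmeth >= 1`).
#' @param context `"CpG"` (endogenous methylation) or `"GpC"` (accessibility).
#' @param cell_id cell identifier.
#' @return An object of class `MethCallSet`: list with `context`, `cell_id`
#'   and `calls` (a `data.table` keyed and sorted by chrom, pos).
#' @export
meth_call_set <- function(calls, context = c("CpG", "GpC"), cell_id = "cell") {
  context <- match.arg(context)
  dt <- data.table::as.data.table(calls)[, c("chrom", "pos", "meth", "unmeth")]
  if (nrow(dt)) {
    if (any(dt$meth < 0) || any(dt$unmeth < 0))
      abort("negative read counts in methylation calls")
    zero <- dt$meth + dt$unmeth == 0
    if (any(zero)) {
      warn("dropping %d call(s) with zero total reads", sum(zero))
      dt <- dt[!zero]
    }
    dt <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
             by = c("chrom", "pos")]
    data.table::setorder(dt, chrom, pos)
  }
  structure(list(context = context, cell_id = as.character(cell_id),
                 calls = dt),
            class = "MethCallSet")
}

#' @export
print.MethCallSet <- function(x, ...) {
  cat(sprintf("MethCallSet (%s) for cell '%s': %d sites\n",
              x$context, x$cell_id, nrow(x$calls)))
  invisible(x)
}

#' Construct a genomic feature set
#'
#' Named genomic intervals grouped into classes (e.g. promoters, lineage
#' enhancer catalogues). Input coordinates follow the BED convention
#' (0-based, half-open); they are converted once, here, to the 1-based closed
#' convention used throughout the package, so that a methylation call at
#' 1-based position p lies in a feature iff start1 <= p <= end1.
#'
#' @param chrom,start,end vectors of interval coordinates (0-based half-open).
#' @param name feature names, unique within a class.
#' @param class_label one class label per interval (recycled if scalar).
#' @return A `GRanges` with metadata columns `name` and `class`.
#' @export
feature_set <- function(chrom, start, end, name = NULL, class_label = "feature") {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n); end <- rep_len(end, n)
  bad <- which(start >= end)
  if (length(bad))
    abort("feature interval %d has start >= end (%s:%s-%s)",
          bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]])
  name <- name %||% sprintf("feature_%d", seq_len(n))
  class_label <- rep_len(as.character(class_label), n)
  if (anyDuplicated(paste(class_label, name)))
    abort("feature names must be unique within a class")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  S4Vectors::mcols(gr)$name <- as.character(name)
  S4Vectors::mcols(gr)$class <- class_label
  gr
}

#' Validate a per-cell annotation table
#'
#' @param ann data.frame with at least `cell_id`, `embryo_id`, `genotype` and
#'   `cell_type` columns; reference cells additionally carry `stage_label`.
#' @param cm optional `CountMatrix` whose cells must exactly cover `ann`.
#' @return the validated annotation `data.frame` (invisibly unchanged).
#' @export
validate_annotation <- function(ann, cm = NULL) {
  need <- c("cell_id", "embryo_id", "genotype", "cell_type")
  miss <- setdiff(need, names(ann))
  if (length(miss)) abort("annotation lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(ann$cell_id)) abort("duplicate cell_id in annotation")
  if (!is.null(cm)) {
    if (!setequal(ann$cell_id, cell_ids(cm)) ||
        length(ann$cell_id) != length(cell_ids(cm)))
      abort("annotation cells do not match count matrix cells")
  }
  ann
}
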