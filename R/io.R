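#' Read a 10x-style MatrixMarket count matrix
#'
#' Reads a MatrixMarket coordinate triplet file together with the plain-text
#' barcode and feature lists that index it (one entry per line). Follows the
#' 10x Genomics layout: matrix rows are features and columns are barcodes;
#' the result is transposed to the package's cells-by-genes orientation.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param barcodes_path path to the barcode list (one cell id per line).
#' @param features_path path to the feature list; first column is the gene
#'   identifier, an optional second (tab-separated) column is the gene symbol.
#' @return a [count_matrix()].
#' @export
read_counts <- function(matrix_path, barcodes_path, features_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feat <- utils::read.table(features_path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
  if (ncol(m) != length(barcodes))
    abort("matrix has %d columns but barcode file lists %d cells",
          ncol(m), length(barcodes))
  if (nrow(m) != nrow(feat))
    abort("matrix has %d rows but feature file lists %d genes",
          nrow(m), nrow(feat))
  vals <- m@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    abort("count matrix contains negative or non-integer entries")
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, feat[[1]])
  count_matrix(m, gene_names = if (ncol(feat) >= 2) feat[[2]] else NULL)
}

#' Write a CountMatrix in 10x-style MatrixMarket layout
#'
#' @param cm a `CountMatrix`.
#' @param dir output directory; `matrix.mtx`, `barcodes.tsv` and
#'   `features.tsv` are created inside it.
#' @return the directory path, invisibly.
#' @export
write_counts <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cm$counts), file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(cm), file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(gene_ids(cm), cm$gene_names),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read per-cell methylation calls (Bismark-coverage dialect)
#'
#' Expects a tab-separated file with columns chrom, start, end, methylated
#' read count, unmethylated read count; positions are 1-based as written by
#' Bismark's coverage output. A header line is auto-detected and skipped.
#' Duplicate positions are merged by summing counts; rows with zero total
#' reads are dropped with a warning.
#'
#' @param path TSV file (optionally gzipped).
#' @param context `"CpG"` or `"GpC"`.
#' @param cell_id cell identifier; defaults to the file name stem.
#' @param collapse_strands if `TRUE`, calls at adjacent positions (p, p+1) on
#'   the same chromosome — a symmetric CpG seen on both strands — are merged
#'   into a single record at the lower position. Use when the upstream caller
#'   did not already collapse strands.
#' @return a [meth_call_set()].
#' @export
read_meth_calls <- function(path, context = c("CpG", "GpC"), cell_id = NULL,
                            collapse_strands = FALSE) {
  context <- match.arg(context)
  cell_id <- cell_id %||% sub("\\.(tsv|txt|cov)(\\.gz)?$", "", basename(path))
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          col.names = c("chrom", "start", "end",
                                        "meth", "unmeth")[1:5])
  calls <- data.table::data.table(chrom = as.character(dt$chrom),
                                  pos = as.integer(dt$start),
                                  meth = as.numeric(dt$meth),
                                  unmeth = as.numeric(dt$unmeth))
  mcs <- meth_call_set(calls, context = context, cell_id = cell_id)
  if (collapse_strands) mcs <- collapse_strand_pairs(mcs)
  mcs
}

#' Merge symmetric-CpG strand pairs at adjacent positions
#' @param mcs a `MethCallSet`
#' @return a `MethCallSet` with (p, p+1) pairs merged at position p
#' @export
collapse_strand_pairs <- function(mcs) {
  dt <- mcs$calls
  if (!nrow(dt)) return(mcs)
  # greedy left-to-right pairing within chromosome; positions already sorted
  out <- dt[, {
    p <- pos; m <- meth; u <- unmeth
    keep_pos <- integer(0); keep_m <- numeric(0); keep_u <- numeric(0)
    i <- 1L
    while (i <= length(p)) {
      if (i < length(p) && p[i + 1L] == p[i] + 1L) {
        keep_pos <- c(keep_pos, p[i])
        keep_m <- c(keep_m, m[i] + m[i + 1L])
        keep_u <- c(keep_u, u[i] + u[i + 1L])
        i <- i + 2L
      } else {
        keep_pos <- c(keep_pos, p[i]); keep_m <- c(keep_m, m[i])
        keep_u <- c(keep_u, u[i])
        i <- i + 1L
      }
    }
    list(pos = keep_pos, meth = keep_m, unmeth = keep_u)
  }, by = "chrom"]
  meth_call_set(out, context = mcs$context, cell_id = mcs$cell_id)
}

#' Write methylation calls in the Bismark-coverage dialect
#' @param mcs a `MethCallSet`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_meth_calls <- function(mcs, path) {
  dt <- mcs$calls
  utils::write.table(
    data.frame(dt$chrom, dt$pos, dt$pos, dt$meth, dt$unmeth),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file into a feature set
#'
#' Coordinates are 0-based half-open on disk and converted exactly once, here,
#' to the package's 1-based closed convention (see [feature_set()]).
#' `track`/`browser`/comment lines are skipped.
#'
#' @param path BED file.
#' @param class_label class assigned to every interval; defaults to the file
#'   name stem (e.g. `erythroid_enhancers.bed` -> `erythroid_enhancers`).
#' @return a `GRanges` feature set.
#' @export
read_bed <- function(path, class_label = NULL) {
  class_label <- class_label %||% sub("\\.bed(\\.gz)?$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) abort("no intervals in %s", path)
  fields <- strsplit(lines[idx], "[\t ]+")
  ncols <- lengths(fields)
  if (any(ncols < 3))
    abort("line %d of %s has fewer than 3 columns", idx[which(ncols < 3)[1]], path)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    abort("malformed coordinate on line %d of %s", idx[bad[1]], path)
  bad <- which(start >= end)
  if (length(bad))
    abort("start >= end on line %d of %s", idx[bad[1]], path)
  name <- vapply(seq_along(fields), function(i)
    if (ncols[i] >= 4) fields[[i]][4] else sprintf("%s_%d", class_label, i), "")
  feature_set(chrom, start, end, name = name, class_label = class_label)
}

#' Write a feature set as BED4 (0-based half-open)
#' @param fs a `GRanges` feature set
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(fs, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(fs)),
                   start = GenomicRanges::start(fs) - 1L,
                   end = GenomicRanges::end(fs),
                   name = S4Vectors::mcols(fs)$name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
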