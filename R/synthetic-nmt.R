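#' Specification of the synthetic single-cell epigenome
#'
#' Defines the methylation/accessibility landscape emulated along a
#' differentiation trajectory. Each feature class has a baseline CpG
#' methylation rate; classes on the trajectory additionally have a WT
#' endpoint rate reached linearly in latent time. Classes flagged
#' `tet_dependent` stay at their baseline in TET triple-knockout cells
#' (active demethylation abolished), while a genome-wide passive loss —
#' the `global_demethylation_slope`, applied additively to every CpG site in
#' both genotypes — continues regardless. GpC accessibility follows its own
#' per-class baseline/endpoint and is genotype-independent (the knockout does
#' not block enhancer opening).
#'
#' @param feature_classes data.frame with columns `class`, `meth_base`,
#'   `meth_endpoint` (NA = no planted trajectory), `tet_dependent` (logical),
#'   `acc_base`, `acc_endpoint` (NA = constant). The default plants
#'   TET-dependent demethylation (0.8 -> 0.2) at erythroid enhancers,
#'   constitutively low methylation at promoters, and static high methylation
#'   at enhancers of other lineages.
#' @param background_meth_base,background_acc rates at sites outside any
#'   feature (flanking DNA).
#' @param global_demethylation_slope additive genome-wide CpG loss per unit
#'   latent time, both genotypes.
#' @param site_density expected CpG (and, independently, GpC) sites per bp.
#' @param cpg_coverage,gpc_coverage probability that a site is observed in a
#'   given cell (single-cell bisulfite data are sparse; most features are
#'   unobserved in most cells).
#' @param read_lambda reads per covered site are `1 + Poisson(read_lambda)`.
#' @param flank bp of flanking background sequence simulated on each side of
#'   a feature (must cover the profile flank).
#' @param seed integer seed.
#' @return an object of class `EpigenomeSpec`.
#' @export
epigenome_spec <- function(feature_classes = NULL,
                           background_meth_base = 0.8,
                           background_acc = 0.25,
                           global_demethylation_slope = 0.15,
                           site_density = 0.04,
                           cpg_coverage = 0.2,
                           gpc_coverage = 0.25,
                           read_lambda = 0.3,
                           flank = 2500,
                           seed = 1L) {
  if (is.null(feature_classes))
    feature_classes <- data.frame(
      class = c("promoters", "erythroid_enhancers", "other_enhancers"),
      meth_base = c(0.10, 0.80, 0.80),
      meth_endpoint = c(NA, 0.20, NA),
      tet_dependent = c(FALSE, TRUE, FALSE),
      acc_base = c(0.35, 0.25, 0.25),
      acc_endpoint = c(NA, 0.40, NA),
      stringsAsFactors = FALSE)
  rates <- c(feature_classes$meth_base, feature_classes$acc_base,
             background_meth_base, background_acc,
             stats::na.omit(feature_classes$meth_endpoint),
             stats::na.omit(feature_classes$acc_endpoint))
  assert_in_range(rates, 0, 1, "methylation/accessibility rates")
  structure(list(feature_classes = feature_classes,
                 background_meth_base = background_meth_base,
                 background_acc = background_acc,
                 global_demethylation_slope = global_demethylation_slope,
                 site_density = site_density,
                 cpg_coverage = cpg_coverage, gpc_coverage = gpc_coverage,
                 read_lambda = read_lambda, flank = flank,
                 seed = as.integer(seed)),
            class = "EpigenomeSpec")
}

#' Lay out a synthetic feature catalogue
#'
#' Features of each class are placed sequentially on one synthetic
#' chromosome, spaced so that profile windows of neighbouring features never
#' overlap.
#'
#' @param epi_spec an `EpigenomeSpec`.
#' @param n_per_class named integer vector: features per class (names must be
#'   classes of the spec).
#' @param width feature width in bp.
#' @return a `GRanges` feature set (see [feature_set()]).
#' @export
simulate_feature_set <- function(epi_spec, n_per_class = NULL, width = 1000) {
  classes <- epi_spec$feature_classes$class
  if (is.null(n_per_class))
    n_per_class <- stats::setNames(rep(20L, length(classes)), classes)
  unknown <- setdiff(names(n_per_class), classes)
  if (length(unknown)) abort("unknown feature class(es): %s",
                             paste(unknown, collapse = ", "))
  cls <- rep(names(n_per_class), n_per_class)
  n <- length(cls)
  gap <- 2 * epi_spec$flank + 1000
  start0 <- (seq_len(n) - 1) * (width + gap) + epi_spec$flank
  feature_set(chrom = rep("chrS", n), start = start0, end = start0 + width,
              name = sprintf("%s_%03d", cls,
                             unlist(lapply(n_per_class, seq_len))),
              class_label = cls)
}

#' True site rate of the synthetic epigenome model
#'
#' @param epi_spec an `EpigenomeSpec`.
#' @param class feature class name, or `"background"` for flanking sites.
#' @param time latent time in `[0, 1]`.
#' @param genotype `"WT"` or `"TetTKO"`.
#' @param context `"CpG"` or `"GpC"`.
#' @return rate(s) in `[0, 1]` (vectorized over `time`).
#' @export
nmt_true_rate <- function(epi_spec, class, time, genotype = "WT",
                          context = c("CpG", "GpC")) {
  context <- match.arg(context)
  assert_in_range(time, 0, 1, "latent time")
  fc <- epi_spec$feature_classes
  if (identical(class, "background")) {
    if (context == "GpC") return(rep(epi_spec$background_acc, length(time)))
    return(pmin(1, pmax(0, epi_spec$background_meth_base -
                          epi_spec$global_demethylation_slope * time)))
  }
  i <- match(class, fc$class)
  if (is.na(i)) abort("unknown feature class '%s'", class)
  if (context == "GpC") {
    r <- if (is.na(fc$acc_endpoint[i])) rep(fc$acc_base[i], length(time)) else
      fc$acc_base[i] + (fc$acc_endpoint[i] - fc$acc_base[i]) * time
    return(pmin(1, pmax(0, r)))
  }
  blocked <- genotype == "TetTKO" && fc$tet_dependent[i]
  r <- if (is.na(fc$meth_endpoint[i]) || blocked)
    rep(fc$meth_base[i], length(time)) else
    fc$meth_base[i] + (fc$meth_endpoint[i] - fc$meth_base[i]) * time
  pmin(1, pmax(0, r - epi_spec$global_demethylation_slope * time))
}

# site table for one context: position, class of containing feature or
# "background" if in a feature's flank
lay_sites <- function(epi_spec, fs) {
  starts <- GenomicRanges::start(fs); ends <- GenomicRanges::end(fs)
  cls <- S4Vectors::mcols(fs)$class
  out <- vector("list", length(fs))
  for (i in seq_along(fs)) {
    lo <- starts[i] - epi_spec$flank; hi <- ends[i] + epi_spec$flank
    pos <- lo:hi
    pos <- pos[stats::runif(length(pos)) < epi_spec$site_density]
    out[[i]] <- data.table::data.table(
      pos = pos,
      class = ifelse(pos >= starts[i] & pos <= ends[i], cls[i], "background"))
  }
  data.table::rbindlist(out)
}

#' Simulate coupled CpG + GpC single-cell bisulfite calls along a trajectory
#'
#' Sites are laid out once (feature bodies carry their class's rate, flanks
#' the background rate); each cell then observes a sparse random subset of
#' sites with `1 + Poisson` read depth, and methylated read counts are
#' binomial at the true rate for the cell's latent time and genotype (see
#' [nmt_true_rate()]).
#'
#' @param epi_spec an `EpigenomeSpec`.
#' @param fs feature set from [simulate_feature_set()] (or any `GRanges`
#'   whose classes the spec knows).
#' @param time numeric vector of latent times in `[0, 1]`, one per cell.
#' @param genotype character vector (`"WT"`/`"TetTKO"`), recycled.
#' @return list with `cpg` and `gpc` (lists of `MethCallSet`, one per cell)
#'   and `truth` (data.frame: cell_id, genotype, time).
#' @export
simulate_nmt_cells <- function(epi_spec, fs, time, genotype = "WT") {
  assert_in_range(time, 0, 1, "latent time")
  n_cells <- length(time)
  genotype <- rep_len(genotype, n_cells)
  set.seed(epi_spec$seed)
  sites <- list(CpG = lay_sites(epi_spec, fs), GpC = lay_sites(epi_spec, fs))
  cov_p <- c(CpG = epi_spec$cpg_coverage, GpC = epi_spec$gpc_coverage)
  ids <- sprintf("nmt_cell_%04d", seq_len(n_cells))
  out <- list(CpG = vector("list", n_cells), GpC = vector("list", n_cells))
  for (ctx in c("CpG", "GpC")) {
    st <- sites[[ctx]]
    classes <- unique(st$class)
    for (c in seq_len(n_cells)) {
      obs <- st[stats::runif(nrow(st)) < cov_p[ctx]]
      total <- 1L + stats::rpois(nrow(obs), epi_spec$read_lambda)
      rate_by_class <- vapply(classes, function(cl)
        nmt_true_rate(epi_spec, cl, time[c], genotype[c], ctx), 0)
      r <- rate_by_class[match(obs$class, classes)]
      meth <- stats::rbinom(nrow(obs), total, r)
      out[[ctx]][[c]] <- meth_call_set(
        data.frame(chrom = "chrS", pos = obs$pos,
                   meth = meth, unmeth = total - meth),
        context = ctx, cell_id = ids[c])
    }
  }
  list(cpg = out$CpG, gpc = out$GpC,
       truth = data.frame(cell_id = ids, genotype = genotype, time = time,
                          stringsAsFactors = FALSE))
}
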