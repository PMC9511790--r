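---
title: "Methods and models behind scembryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind scembryo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`scembryo` packages the computational workflow used to phenotype
DNA-methylation-machinery knockouts (*Dnmt1*, *Dnmt3a*, *Dnmt3b*, *Tet*
triple knockout) in mouse embryos at early organogenesis with single-cell
multi-omics. This vignette is the package's own account of the models and
procedures it implements, why the defaults are what they are, and what the
synthetic benchmarks do and do not demonstrate.

## The analysis in one paragraph

Query embryos (knockout and wildtype) are profiled by single-cell RNA-seq.
Each cell is given a cell-type identity by mapping it into a labelled
multi-stage reference atlas and letting its 30 nearest reference neighbours
vote. Per-embryo cell-type proportions then quantify compositional
phenotypes (as log2 ratios against a wildtype baseline) and assign each
embryo a developmental stage by proximity to staged reference embryos.
Expression phenotypes are tested per cell type on embryo-level pseudobulk
profiles under a negative-binomial model, interpreted through reference
marker-gene sets. For cells profiled with joint RNA + bisulfite readouts
(scNMT-style), CpG methylation and GpC accessibility are quantified over
regulatory elements under a binomial model, compared between genotypes, and
followed along a diffusion-map pseudotime of the erythroid trajectory.

## Quality control and normalization

Cell-level RNA gates are platform-specific because droplet 3' libraries and
deep plate-based libraries have different count and contamination scales:
droplet cells need ≥ 1500 UMIs, ≤ 30% mitochondrial and ≤ 35% ribosomal
reads; plate cells need ≥ 4000 reads, ≤ 10% mitochondrial and ≤ 20%
ribosomal reads. All comparisons are inclusive — a cell exactly at a bound
passes. Bisulfite cells need ≥ 5000 covered CpGs with ≥ 50% global
methylation, and ≥ 10000 covered GpCs with global accessibility in
[10%, 40%] (the GpC upper bound rejects failed enzymatic labelling and
conversion artefacts).

A covered site's methylation state is *binarized*: rate
`meth / (meth + unmeth)` thresholded at 0.5, with exactly 0.5 counted as
methylated. The tie direction is an explicit convention so results are
deterministic; at single-cell coverage most sites carry one read and the
binarized state is simply that read's call. A cell's global rate is the
mean of binarized states over its covered sites.

Size factors come in two modes. `"library"` scales with total counts.
`"pooled"` is the pool-and-deconvolve estimator of scran (counts summed
over cell pools, a least-squares system solved for per-cell factors),
robust to differential expression between cells; below 50 cells the
deconvolution system is poorly conditioned and the library mode is used
instead. Factors are rescaled to mean 1 so normalized counts stay on the
count scale.

## Atlas mapping and label transfer

Reference and query are normalized together, the top 2000 highly variable
genes are taken (variance of log1p expression in excess of a local
polynomial mean-variance trend), each cell's expression vector is
cosine-normalized, and a joint PCA (50 components) is fitted on the
concatenated matrix. Cosine normalization puts both batches on a common
scale, which is also what makes a fixed kernel bandwidth meaningful below.
Component signs are fixed (largest-magnitude loading positive) so the
embedding is reproducible to the bit.

Batch correction matches mutual nearest neighbours (MNN) between the two
batches in PCA space (pairing depth `mnn_k = 20`). Each query cell is
shifted by a Gaussian-kernel-weighted average of pair difference vectors
(reference minus query member). The kernel (bandwidth `mnn_sigma = 0.1` in
cosine-normalized PCA units) is anchored at pair *midpoints*: the two pairs
of a symmetric duo — reference *j* with query *i*, and reference *i* with
query *j* — share a midpoint and hence a weight, so their within-batch
components cancel and only the systematic batch displacement survives.
This gives exactly zero correction for identical batches and exact
recovery of a constant batch shift, two properties the package tests
directly. Reference coordinates are never moved.

Labels transfer by majority voting: each query cell's `k = 30` nearest
reference cells (Euclidean distance, corrected space) are tallied by type
and the argmax wins. This is equivalently the mode of a Dirichlet
posterior over type frequencies with a unit pseudo-count, which is why the
assignment confidence is reported simply as the winning count over *k*.
Ties break toward the type whose tied neighbours are nearer in summed
distance, then lexicographically — again a determinism convention. *k* is
the one mapping constant treated as part of the method; the HVG count, PC
count and kernel settings are exposed configuration.

## Composition and staging

Per-embryo proportions are computed over the shared cell-type vocabulary
with a pseudocount of 1 cell per type, which keeps log2 ratios finite when
a type is absent from an embryo. Shifts are `log2(p_KO / baseline)` with
the baseline either the arithmetic mean of wildtype embryo proportions or,
for chimaeras, the matched host embryo of the same animal (host embryos
carry no link and serve only as baselines).

One consequence worth knowing when interpreting shifts: because proportions
renormalize, depleting a type whose baseline share is `p0` by a factor `f`
yields an observed shift of `log2(f) − log2(1 − (1 − f)·p0)`, not
`log2(f)`. For a rare type the attenuation is negligible; for a 20% type a
4-fold depletion reads as about −1.77 rather than −2. The package's
recovery benchmark therefore plants its depletion on the rarest type.

Staging fits a PCA on the row-stacked proportion matrix of query plus
staged reference embryos. Rows are centered but not scaled — proportions
already share a scale and scaling would inflate rare-type noise. The
number of retained components defaults to (number of stages − 1), the
dimensionality that separates stage centroids. A query embryo's raw score
for a stage is the mean inverse Euclidean distance to that stage's
reference embryos (mean rather than minimum, for robustness to a single
odd reference embryo); scores are minmax-normalized across stages so the
best stage scores exactly 1. A zero distance (identical composition)
promotes that stage to the maximum before normalization, and an all-equal
score vector maps to all 1s.

## Pseudobulk differential expression and markers

Counts are summed per embryo within a cell type — embryos, not cells, are
the unit of replication, so the test is honest about biological variance.
Samples backed by fewer than 10 cells are dropped, and each genotype needs
at least 2 surviving samples. Normalization factors are the
median-of-ratios estimator (per sample, the median over
all-samples-nonzero genes of count over geometric mean).

Testing fits, per gene, a negative-binomial GLM with log link and an
offset built from the sample's factor and library size; tagwise
dispersions are shrunk toward a mean-dispersion trend by empirical Bayes
and the group coefficient is tested with a quasi-likelihood F-test. This
is the standard edgeR machinery, which the package drives directly; a
likelihood-ratio mode (`method = "lrt"`) is available and passes the same
calibration benchmarks. Genes with all-zero counts are excluded from
testing *and* from the multiple-testing family; when analysis is
restricted to a marker list, the BH family is the restricted set.
Significance requires BH-adjusted p ≤ 0.01 and |log2FC| ≥ 1.

The reported log2 fold change is computed from normalized group means with
a gene-relative prior of 1% of the gene's mean normalized count. Two
properties motivated this over a fixed pseudocount: the estimate is
exactly invariant to jointly rescaling counts and factors (a fixed
pseudocount cannot be, since it breaks homogeneity), and genes observed in
only one group get a finite, capped estimate (log2(201) ≈ 7.65) instead of
an infinite one. P-values are unaffected.

Marker genes: for each of C cell types, DE is run against each of the
other C − 1 types; a gene marks a type iff it is significantly
*up*-regulated there in strictly more than 75% of those comparisons.
"Strictly" matters: with C = 5, being DE in 3 of 4 comparisons (exactly
75%) does not qualify. A gene can mark several types once C − 1 > 4. The
rule degenerates below C = 3 and is rejected there.

## Epigenome quantification

Feature-level rates follow a binomial model: trials are a cell's covered
sites inside the feature, successes its binarized-methylated sites.
Features with zero covered sites are *missing*, never zero — at
single-cell sparsity the distinction is essential, and downstream
statistics (cell means, group medians) are computed over observed entries
only. A site inside overlapping features counts toward each.

Metaprofiles center on `floor((start + end) / 2)` of each feature (BED
coordinates) and tile ±2 kb in half-open 50 bp windows. Within a cell,
sites are pooled across all features of a class (site-weighted) into
per-window rates; mean and standard deviation are then taken *across
cells*, so the ribbon reflects cell-to-cell variability, with cells
lacking coverage in a window excluded from that window.

Genotype comparisons per feature class use each cell's mean rate over the
class's covered features; the report gives group medians, their
difference, a Wilcoxon rank-sum p-value and BH adjustment across classes.
The effect size is the primary readout; the test is secondary and is
skipped below 3 cells per group.

Coordinate conventions are fixed once, in the readers: BED is 0-based
half-open, bisulfite call positions are 1-based, and both are converted on
input to the 1-based closed convention used throughout, so no downstream
code reasons about conventions. Whether symmetric CpG strand pairs were
already collapsed upstream is not knowable from the files; the reader
exposes `collapse_strands` rather than guessing.

## Pseudotime

The trajectory is a diffusion map: a Gaussian kernel on Euclidean
distances with local scales (each cell's scale is its distance to the 5th
neighbour), density normalization so the embedding reflects geometry
rather than sampling density, and the top non-trivial eigenvectors of the
resulting transition operator. The first diffusion component is the
trajectory axis — the sorted populations follow a single lineage, and
branching inference is out of scope. Because an eigenvector's sign is
arbitrary, the axis is oriented so pseudotime correlates positively with
an anchor gene known to rise along the trajectory (an embryonic
haemoglobin for primitive erythropoiesis); pseudotime is the rank of the
oriented component rescaled to exactly [0, 1]. A disconnected kernel graph
is an error suggesting a larger scale, not a silent partial embedding.

Smoothed curves are LOESS: tricube-weighted local linear regression over
the `span` fraction of nearest points (default 0.5, 100-point grid),
evaluated exactly (no interpolation surface) so each grid value equals the
direct weighted-least-squares fit — a property the tests check point by
point.

## The synthetic data generators

The generators are first-class, tested code; their defaults *are* the
study conditions every benchmark runs under.

**Reference atlas.** Five cell types across three stages (E7.5, E8.0,
E8.5); per-stage type proportions drift so early types fade as late types
rise, making stages separable from composition alone. Counts are negative
binomial with gene-level means (gamma-distributed baseline), a shared
dispersion of 0.1, log-normal per-cell depth (sdlog 0.3, mean 2500), and
20 disjoint marker genes per type up-shifted by log2FC = 3. The NB family
matches the DE stage's model, so calibration and power benchmarks are
well-posed.

**Query embryos.** Drawn from a perturbed, renormalized composition
(proportion fold changes and/or a stage delay), with optional
per-cell-type gene dysregulation, and a per-gene log-normal batch scaling
(sdlog 0.25) relative to the atlas so the MNN stage has real work to do.
True cell types, planted effects and batch factors are emitted as ground
truth.

**Coupled trajectory cells.** Features (promoters, erythroid enhancers,
other-lineage enhancers) are laid on a synthetic chromosome with ~0.04
sites/bp in bodies and flanks. Site rates follow: a baseline per class
(promoters 0.10, enhancers and background 0.80); a TET-dependent erythroid
enhancer trajectory 0.8 → 0.2 in wildtype, absent in the TET triple
knockout; a genome-wide passive loss of 0.15 per unit latent time in both
genotypes (replication-linked demethylation continues without TET); and
GpC accessibility that opens at erythroid enhancers (0.25 → 0.40) in both
genotypes, because enhancer opening does not require demethylation.
Coverage is sparse (each site observed with probability 0.2–0.25 per cell,
1 + Poisson(0.3) reads), so aggregation must handle missing features, as
in real single-cell bisulfite data. Matched RNA gives a third of genes
log-linear expression in latent time, including a strongly rising anchor
gene.

Benchmark problem sizes, chosen as desk-scale stand-ins for the study's:
5000 reference + 2000 query cells for label transfer; 10 + 10 embryos of
1000 cells for composition; a 60-feature-per-class catalogue with 120
spread-trajectory cells for pseudotime and global-decline curves and a
sorted late-trajectory "erythroid" cohort of 60 cells per genotype —
paper-scale for sorted erythroid populations — for profiles and genotype
comparisons.

What passing these benchmarks shows: the estimators recover effects they
were designed for, at realistic sparsity and noise, with correct
calibration. What they do not show: robustness to features of real data
the generators omit — ambient RNA and doublets, batch effects that are not
per-gene scalings, cell types absent from the reference, chromosome-scale
methylation heterogeneity, and imprinting or repeat biology.

## Numerical and degenerate-input conventions

Eigen/SVD component signs are fixed by the largest-loading rule.
Distance ties in voting and staging break deterministically (stated
above). Duplicate methylation calls at one position merge by summing
reads; zero-total rows drop with a warning. Zero mutual pairs, a
disconnected diffusion kernel, an all-zero anchor gene, `span × n < 3`,
and `k` exceeding the reference size are hard errors, not silent
fallbacks. Pipeline TSVs are written with fixed floating-point formatting,
and each stage records parameter hashes and output checksums in a JSON
manifest, so identical configurations and seeds reproduce outputs
byte-for-byte and unchanged stages are skipped on re-run.

## Known limitations

Label transfer supports exactly two batches (reference and query);
multi-batch integration is out of scope. Compositional shifts are reported
as effect sizes without a formal compositional test. The marker rule
inherits the reference atlas's granularity. Pseudotime is single-branch.
The epigenome module quantifies rates over supplied annotations; it does
not call differentially methylated single CpGs, model hydroxymethylation,
or quantify repeat elements.
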