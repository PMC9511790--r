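Package: scembryo
Title: Knockout-Versus-Wildtype Single-Cell Multi-Omics Analysis of Mouse Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing knockout and wildtype
    mouse embryos with single-cell multi-omics readouts. Provides reference-atlas
    cell-type label transfer by mutual-nearest-neighbour batch correction and
    joint k-nearest-neighbour majority voting, cell-type composition and
    embryo-staging analysis, pseudobulk negative-binomial differential
    expression with a pairwise marker-gene rule, diffusion-map pseudotime with
    LOESS expression curves, and single-cell bisulfite CpG methylation and GpC
    accessibility quantification over regulatory elements, including
    feature-centred metaprofiles. Ships a synthetic-data generator that
    emulates the structure of such studies (a labelled multi-stage reference
    atlas, perturbed query embryos, and coupled RNA+CpG+GpC cells along a
    differentiation trajectory) so every stage can be exercised and validated
    end-to-end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    scran,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
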