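#' SweepCNV: case-control selective-sweep and copy-number scans
#'
#' Downstream population-genomic analysis for small case-control
#' resequencing cohorts: windowed ZFst sweep scanning, read-depth CNV
#' calling with Vst differentiation and genotype coding, a depth-normalized
#' region presence/absence test, transition/transversion accounting,
#' hypergeometric gene-set enrichment, and a ground-truth-labelled cohort
#' simulator that makes every stage verifiable at desk scale. See
#' `vignette("SweepCNV-methods")` for the statistical models and the
#' design choices behind them.
#'
#' @keywords internal
#' @import methods
#' @importFrom BiocGenerics sort start end width
#' @importFrom GenomeInfoDb seqnames
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
"_PACKAGE"
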