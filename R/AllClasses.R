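NULL

## ---------------------------------------------------------------------------
## PopulationSplit
## ---------------------------------------------------------------------------

#' Case/control sample grouping
#'
#' Holds the two disjoint, non-empty sample groups every differentiation
#' statistic in the package (window Fst, region Vst) is computed between.
#'
#' @slot caseSamples character vector of case sample names.
#' @slot controlSamples character vector of control sample names.
#'
#' @export
setClass("PopulationSplit",
    representation(caseSamples = "character", controlSamples = "character"))

setValidity("PopulationSplit", function(object) {
    msg <- character()
    if (length(object@caseSamples) == 0L)
        msg <- c(msg, "caseSamples must be non-empty")
    if (length(object@controlSamples) == 0L)
        msg <- c(msg, "controlSamples must be non-empty")
    ov <- intersect(object@caseSamples, object@controlSamples)
    if (length(ov))
        msg <- c(msg, paste0("samples in both groups: ",
                             paste(ov, collapse = ", ")))
    if (anyDuplicated(object@caseSamples) || anyDuplicated(object@controlSamples))
        msg <- c(msg, "duplicated sample names within a group")
    if (length(msg)) msg else TRUE
})

#' Construct a PopulationSplit
#'
#' @param caseSamples,controlSamples character vectors of sample names; the
#'   groups must be disjoint and non-empty.
#' @return A [PopulationSplit-class] object.
#' @examples
#' PopulationSplit(c("case1", "case2"), paste0("ctrl", 1:6))
#' @export
PopulationSplit <- function(caseSamples, controlSamples) {
    new("PopulationSplit",
        caseSamples = as.character(caseSamples),
        controlSamples = as.character(controlSamples))
}

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic case-control cohort
#'
#' Describes the simulated genome (chromosome count and length), the cohort
#' design (cases vs controls), SNP density and the baseline allele-frequency
#' distribution, plus the planted ground-truth features: sweep intervals with
#' group-specific allele frequencies, copy-number intervals with
#' group-specific integer copy numbers, and an optional full/partial region
#' deletion restricted to named samples.
#'
#' Planted intervals are 1-based inclusive, must lie within the chromosome
#' and must not overlap one another on the same chromosome.
#'
#' @slot nChromosomes integer, number of simulated chromosomes (named
#'   `chr1..chrN`).
#' @slot chromosomeLength integer, length of every chromosome in bp.
#' @slot nCases,nControls integer group sizes (samples named `case1..`,
#'   `ctrl1..`).
#' @slot snpDensity numeric, expected SNPs per bp.
#' @slot betaShape1,betaShape2 numeric, shape parameters of the Beta
#'   distribution baseline allele frequencies are drawn from.
#' @slot sweeps data.frame with columns `chrom, start, end, caseFreq,
#'   controlFreq`.
#' @slot cnvs data.frame with columns `chrom, start, end, caseCN, controlCN`
#'   (non-negative integer copy numbers; diploid = 2).
#' @slot deletion list with elements `chrom, start, end, samples,
#'   residualFraction`, or an empty list.
#' @slot tsProbability numeric, probability that a simulated alt allele is
#'   the transition partner of the ref base (A<->G, C<->T); the remaining
#'   mass is split over the two transversion partners.
#' @slot meanDepth numeric, expected read count per 800 bp window per sample.
#' @slot lowQualFraction numeric, fraction of SNP sites written with QUAL 10
#'   instead of 60 (to exercise quality filters).
#' @slot seed integer master seed; per-output streams are derived from it by
#'   labelled sub-seeding.
#'
#' @export
setClass("SimulationConfig",
    representation(
        nChromosomes = "integer", chromosomeLength = "numeric",
        nCases = "integer", nControls = "integer",
        snpDensity = "numeric", betaShape1 = "numeric", betaShape2 = "numeric",
        sweeps = "data.frame", cnvs = "data.frame", deletion = "list",
        tsProbability = "numeric", meanDepth = "numeric",
        lowQualFraction = "numeric", seed = "integer"))

.checkIntervals <- function(df, L, what, msg) {
    if (nrow(df) == 0L) return(msg)
    if (any(df$start < 1 | df$end > L | df$start > df$end))
        msg <- c(msg, paste0(what, ": interval outside chromosome bounds"))
    msg
}

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nChromosomes < 1L) msg <- c(msg, "need >= 1 chromosome")
    if (object@chromosomeLength < 1) msg <- c(msg, "chromosomeLength must be positive")
    if (object@nCases < 1L || object@nControls < 1L)
        msg <- c(msg, "need >= 1 case and >= 1 control")
    if (object@snpDensity < 0 || object@snpDensity > 1)
        msg <- c(msg, "snpDensity must be in [0, 1]")
    if (object@betaShape1 <= 0 || object@betaShape2 <= 0)
        msg <- c(msg, "Beta shapes must be positive")
    sw <- object@sweeps
    if (nrow(sw) && (any(sw$caseFreq < 0 | sw$caseFreq > 1) ||
                     any(sw$controlFreq < 0 | sw$controlFreq > 1)))
        msg <- c(msg, "sweep allele frequencies must be in [0, 1]")
    cv <- object@cnvs
    if (nrow(cv) && (any(cv$caseCN < 0) || any(cv$controlCN < 0) ||
                     any(cv$caseCN != round(cv$caseCN)) ||
                     any(cv$controlCN != round(cv$controlCN))))
        msg <- c(msg, "copy numbers must be non-negative integers")
    msg <- .checkIntervals(sw, object@chromosomeLength, "sweeps", msg)
    msg <- .checkIntervals(cv, object@chromosomeLength, "cnvs", msg)
    del <- object@deletion
    if (length(del)) {
        if (!all(c("chrom", "start", "end", "samples", "residualFraction") %in%
                 names(del)))
            msg <- c(msg, "deletion needs chrom, start, end, samples, residualFraction")
        else {
            if (del$start < 1 || del$end > object@chromosomeLength ||
                del$start > del$end)
                msg <- c(msg, "deletion: interval outside chromosome bounds")
            if (del$residualFraction < 0 || del$residualFraction > 1)
                msg <- c(msg, "deletion residualFraction must be in [0, 1]")
        }
    }
    ## planted intervals on the same chromosome must not overlap
    iv <- rbind(
        if (nrow(sw)) data.frame(chrom = sw$chrom, start = sw$start,
                                 end = sw$end, id = paste0("sweep", seq_len(nrow(sw)))),
        if (nrow(cv)) data.frame(chrom = cv$chrom, start = cv$start,
                                 end = cv$end, id = paste0("cnv", seq_len(nrow(cv)))),
        if (length(del) && is.null(msg)) data.frame(chrom = del$chrom,
            start = del$start, end = del$end, id = "deletion"))
    if (!is.null(iv) && nrow(iv) > 1L) {
        for (i in seq_len(nrow(iv) - 1L)) for (j in seq(i + 1L, nrow(iv))) {
            if (iv$chrom[i] == iv$chrom[j] &&
                iv$start[i] <= iv$end[j] && iv$start[j] <= iv$end[i])
                msg <- c(msg, paste0("planted intervals overlap: ",
                                     iv$id[i], " and ", iv$id[j]))
        }
    }
    if (object@lowQualFraction < 0 || object@lowQualFraction > 1)
        msg <- c(msg, "lowQualFraction must be in [0, 1]")
    if (object@tsProbability < 0 || object@tsProbability > 1)
        msg <- c(msg, "tsProbability must be in [0, 1]")
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults mirror the study design the simulator emulates: 2 cases vs 6
#' controls, Beta(0.8, 0.8) baseline allele frequencies (a U-shaped folded
#' site-frequency spectrum typical of resequencing SNP calls), and 100x
#' expected reads per 800 bp depth window.
#'
#' @param nChromosomes,chromosomeLength genome shape.
#' @param nCases,nControls group sizes.
#' @param snpDensity expected SNPs per bp.
#' @param betaShape1,betaShape2 baseline allele-frequency Beta shapes.
#' @param sweeps data.frame (`chrom, start, end, caseFreq, controlFreq`) of
#'   planted divergent intervals; `NULL` for none.
#' @param cnvs data.frame (`chrom, start, end, caseCN, controlCN`) of planted
#'   copy-number intervals; `NULL` for none.
#' @param deletion `NULL`, or `list(chrom, start, end, samples,
#'   residualFraction)` describing a region deletion carried by `samples`.
#' @param tsProbability probability that an alt allele is the transition
#'   partner of its ref base; the default 0.7 gives the ts:tv ratio around
#'   2-3 typical of genome-wide SNP calls.
#' @param meanDepth expected reads per depth window per sample.
#' @param lowQualFraction fraction of SNP sites emitted with QUAL 10.
#' @param seed master seed for all derived random streams.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nChromosomes = 1, chromosomeLength = 1e5,
#'                         snpDensity = 1e-3, seed = 1)
#' @export
SimulationConfig <- function(nChromosomes = 1L, chromosomeLength = 1e6,
        nCases = 2L, nControls = 6L, snpDensity = 2e-4,
        betaShape1 = 0.8, betaShape2 = 0.8,
        sweeps = NULL, cnvs = NULL, deletion = NULL, tsProbability = 0.7,
        meanDepth = 100, lowQualFraction = 0, seed = 1L) {
    empty <- function(cols) as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(cols)), cols))
    if (is.null(sweeps))
        sweeps <- empty(c("chrom", "start", "end", "caseFreq", "controlFreq"))
    if (is.null(cnvs))
        cnvs <- empty(c("chrom", "start", "end", "caseCN", "controlCN"))
    sweeps$chrom <- as.character(sweeps$chrom)
    cnvs$chrom <- as.character(cnvs$chrom)
    new("SimulationConfig",
        nChromosomes = as.integer(nChromosomes),
        chromosomeLength = as.numeric(chromosomeLength),
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        snpDensity = snpDensity, betaShape1 = betaShape1,
        betaShape2 = betaShape2, sweeps = sweeps, cnvs = cnvs,
        deletion = if (is.null(deletion)) list() else deletion,
        tsProbability = tsProbability,
        meanDepth = meanDepth, lowQualFraction = lowQualFraction,
        seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated cohort
#'
#' One record per planted feature, as 1-based inclusive [GRanges]:
#' sweep intervals with group allele frequencies, CNV intervals with true
#' per-group copy numbers, and the optional deletion interval with its
#' affected sample list.
#'
#' @slot sweeps,cnvs,deletion GRanges (possibly empty) with feature metadata.
#' @slot caseSamples,controlSamples simulated sample names.
#' @export
setClass("GroundTruth",
    representation(sweeps = "GRanges", cnvs = "GRanges", deletion = "GRanges",
                   caseSamples = "character", controlSamples = "character"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@caseSamples), "cases,",
        length(object@controlSamples), "controls\n")
    cat("  planted sweeps:   ", length(object@sweeps), "\n")
    cat("  planted CNVs:     ", length(object@cnvs), "\n")
    cat("  planted deletion: ", length(object@deletion), "\n")
})

## ---------------------------------------------------------------------------
## VariantSites
## ---------------------------------------------------------------------------

#' Biallelic SNP sites with per-sample genotypes
#'
#' A [GRanges] extension holding one row per biallelic SNP with metadata
#' columns `ref`, `alt` (single bases, `ref != alt`), `qual` (phred site
#' quality), `depth` (site read depth) and `gt`, a character matrix of
#' per-sample diploid calls (`"0/0"`, `"0/1"`, `"1/1"` or `"./."`).
#'
#' @export
setClass("VariantSites", contains = "GRanges")

setValidity("VariantSites", function(object) {
    msg <- character()
    mc <- mcols(object)
    need <- c("ref", "alt", "qual", "depth", "gt")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste0("missing metadata columns: ", paste(miss, collapse = ", ")))
    bases <- c("A", "C", "G", "T")
    if (length(object)) {
        if (!all(mc$ref %in% bases) || !all(mc$alt %in% bases))
            msg <- c(msg, "ref/alt must be single bases in {A,C,G,T}")
        if (any(mc$ref == mc$alt)) msg <- c(msg, "ref must differ from alt")
        if (!is.matrix(mc$gt)) msg <- c(msg, "gt must be a sample matrix")
        if (any(start(object) < 1)) msg <- c(msg, "positions must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn VariantSites-class sample names of the genotype matrix.
#' @param x,object a `VariantSites` object.
#' @export
setMethod("colnames", "VariantSites", function(x) colnames(mcols(x)$gt))

setMethod("show", "VariantSites", function(object) {
    cat("VariantSites:", length(object), "biallelic SNPs,",
        ncol(mcols(object)$gt), "samples (",
        paste(utils::head(colnames(object), 4), collapse = ", "),
        if (ncol(mcols(object)$gt) > 4) ", ..." else "", ")\n", sep = " ")
    callNextMethod()
})

## ---------------------------------------------------------------------------
## DepthWindowMatrix
## ---------------------------------------------------------------------------

#' Sliding-window read counts and normalized copy number
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' sliding genomic windows (800 bp span, 400 bp step by default) and whose
#' columns are samples. The `"counts"` assay holds raw per-window read
#' counts; [normalizeDepth()] adds a `"copyNumber"` assay on the diploid = 2
#' scale. Window size and step are kept in `metadata()`.
#'
#' @export
setClass("DepthWindowMatrix", contains = "RangedSummarizedExperiment")

setValidity("DepthWindowMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    md <- metadata(object)
    if (is.null(md$windowSize) || is.null(md$step))
        msg <- c(msg, "metadata windowSize and step are required")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        if (!all(width(rr) == md$windowSize))
            msg <- c(msg, "all windows must have width == windowSize")
        sq <- as.character(seqnames(rr))
        same <- sq[-1] == sq[-length(sq)]
        d <- diff(start(rr))
        if (any(same & d != md$step))
            msg <- c(msg, "consecutive same-chromosome windows must differ in start by step")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DepthWindowMatrix
#'
#' @param counts integer matrix, windows x samples, with sample column names.
#' @param windows [GRanges] of the window coordinates (1-based inclusive),
#'   one per row of `counts`, ordered by (chromosome, start).
#' @param windowSize,step window span and stride in bp.
#' @return A [DepthWindowMatrix-class].
#' @export
DepthWindowMatrix <- function(counts, windows, windowSize = 800L, step = 400L) {
    stopifnot(nrow(counts) == length(windows), !is.null(colnames(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = windows)
    metadata(se) <- list(windowSize = as.integer(windowSize),
                         step = as.integer(step))
    new("DepthWindowMatrix", se)
}

setMethod("show", "DepthWindowMatrix", function(object) {
    md <- metadata(object)
    cat("DepthWindowMatrix:", nrow(object), "windows (", md$windowSize,
        "bp span /", md$step, "bp step ) x", ncol(object), "samples;",
        "assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CNVRegionSet
## ---------------------------------------------------------------------------

#' Merged copy-number-variable regions
#'
#' A [GRanges] extension with one row per CNV region and matrix metadata
#' columns `cn` (per-sample mean normalized copy number), `cnInteger`
#' (rounded integer copy number), `genotype` (codes `D`, `Ad`, `AA`, `AB`,
#' `BB`, `M` for 0..4 and >= 5 copies) and `meanLog2` (per-sample mean log2
#' copy-number ratio), plus a numeric `vst` column once
#' [regionVst()] has been run.
#'
#' @export
setClass("CNVRegionSet", contains = "GRanges")

setValidity("CNVRegionSet", function(object) {
    mc <- mcols(object)
    if (!"cn" %in% colnames(mc)) return("a 'cn' sample matrix is required")
    if (length(object) && !is.matrix(mc$cn)) return("'cn' must be a matrix")
    if ("vst" %in% colnames(mc) && length(object)) {
        v <- mc$vst[!is.na(mc$vst)]
        if (length(v) && (any(v < -1e-9) || any(v > 1 + 1e-9)))
            return("vst values must lie in [0, 1]")
    }
    TRUE
})

setMethod("show", "CNVRegionSet", function(object) {
    cat("CNVRegionSet:", length(object), "regions,",
        if (length(object)) ncol(mcols(object)$cn) else 0, "samples",
        if ("vst" %in% colnames(mcols(object))) "(Vst computed)" else "",
        "\n")
    callNextMethod()
})
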