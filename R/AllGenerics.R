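#' @rdname PopulationSplit-class
#' @param x a `PopulationSplit`.
#' @export
setGeneric("caseSamples", function(x) standardGeneric("caseSamples"))

#' @rdname PopulationSplit-class
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname PopulationSplit-class
#' @export
setMethod("caseSamples", "PopulationSplit", function(x) x@caseSamples)

#' @rdname PopulationSplit-class
#' @export
setMethod("controlSamples", "PopulationSplit", function(x) x@controlSamples)

#' @rdname PopulationSplit-class
#' @param object a `PopulationSplit`.
#' @export
setMethod("show", "PopulationSplit", function(object) {
    cat("PopulationSplit:", length(object@caseSamples), "cases (",
        paste(object@caseSamples, collapse = ", "), ") vs",
        length(object@controlSamples), "controls (",
        paste(object@controlSamples, collapse = ", "), ")\n")
})

#' Per-window normalized copy number
#'
#' Accessor for the `"copyNumber"` assay added by [normalizeDepth()].
#'
#' @param x a [DepthWindowMatrix-class].
#' @return numeric matrix, windows x samples, diploid = 2 scale.
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))

#' @rdname copyNumber
#' @export
setMethod("copyNumber", "DepthWindowMatrix", function(x) {
    if (!"copyNumber" %in% SummarizedExperiment::assayNames(x))
        stop("no 'copyNumber' assay; run normalizeDepth() first")
    SummarizedExperiment::assay(x, "copyNumber")
})

#' Raw per-window read counts
#'
#' @param x a [DepthWindowMatrix-class].
#' @return integer matrix, windows x samples.
#' @export
setGeneric("depthCounts", function(x) standardGeneric("depthCounts"))

#' @rdname depthCounts
#' @export
setMethod("depthCounts", "DepthWindowMatrix",
    function(x) SummarizedExperiment::assay(x, "counts"))

#' Per-region Vst values
#'
#' @param x a [CNVRegionSet-class] on which [regionVst()] has been run.
#' @return numeric vector of Vst values in the unit interval.
#' @export
setGeneric("vstValues", function(x) standardGeneric("vstValues"))

#' @rdname vstValues
#' @export
setMethod("vstValues", "CNVRegionSet", function(x) {
    if (!"vst" %in% colnames(mcols(x)))
        stop("no 'vst' column; run regionVst() first")
    mcols(x)$vst
})

#' Per-sample CNV genotype codes
#'
#' @param x a [CNVRegionSet-class] on which [genotypeRegions()] has been run.
#' @return character matrix, regions x samples, of codes D/Ad/AA/AB/BB/M.
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))

#' @rdname genotypeCodes
#' @export
setMethod("genotypeCodes", "CNVRegionSet", function(x) {
    if (!"genotype" %in% colnames(mcols(x)))
        stop("no 'genotype' column; run genotypeRegions() first")
    m <- mcols(x)$genotype
    class(m) <- NULL
    m
})
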