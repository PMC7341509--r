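#' Read biallelic SNPs from a VCF
#'
#' Parses a VCF via `VariantAnnotation::readVcf` and returns the biallelic
#' single-nucleotide records as a [VariantSites-class] object. Multi-allelic
#' records, indels and non-ACGT alleles are skipped with a message giving
#' the count, never an error.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return A [VariantSites-class].
#' @export
readBiallelicVariants <- function(path) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altL)
    alt <- rep(NA_character_, length(vcf))
    alt[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    ok <- nAlt == 1L & ref %in% c("A", "C", "G", "T") &
          alt %in% c("A", "C", "G", "T") & !is.na(alt) & ref != alt
    nSkip <- sum(!ok)
    if (nSkip)
        message(nSkip, " non-biallelic-SNP record(s) skipped")
    vcf <- vcf[ok]
    info <- VariantAnnotation::info(vcf)
    depth <- if ("DP" %in% colnames(info)) as.numeric(info$DP)
             else rep(NA_real_, nrow(info))
    gr <- SummarizedExperiment::rowRanges(vcf)
    gt <- VariantAnnotation::geno(vcf)$GT
    ## normalise phased separators so downstream counting sees one dialect
    gt[] <- gsub("|", "/", gt, fixed = TRUE)
    mcols(gr) <- DataFrame(ref = ref[ok], alt = alt[ok],
                           qual = as.numeric(VariantAnnotation::qual(vcf)),
                           depth = depth, gt = I(unname(gt)))
    colnames(mcols(gr)$gt) <- colnames(VariantAnnotation::geno(vcf)$GT)
    names(gr) <- NULL
    new("VariantSites", gr)
}

#' Filter SNP sites on depth and quality
#'
#' Retains sites with read depth strictly greater than `minDepth` and
#' quality at least `minQual` (the asymmetric operators are deliberate:
#' depth is filtered as "reads > 4", quality as "quality >= 20"). Input
#' order is preserved.
#'
#' @param x a [VariantSites-class].
#' @param minDepth sites must have depth `> minDepth` (default 4).
#' @param minQual sites must have quality `>= minQual` (default 20).
#' @return The filtered [VariantSites-class].
#' @export
filterSites <- function(x, minDepth = 4, minQual = 20) {
    stopifnot(is(x, "VariantSites"), minDepth >= 0, minQual >= 0)
    mc <- mcols(x)
    keep <- !is.na(mc$depth) & mc$depth > minDepth &
            !is.na(mc$qual) & mc$qual >= minQual
    x[keep]
}

#' Classify a substitution as transition or transversion
#'
#' Unordered-pair classification of a biallelic substitution:
#' purine-purine (A/G) and pyrimidine-pyrimidine (C/T) exchanges are
#' transitions; the four other pairs (A/T, A/C, G/T, G/C) are
#' transversions. Vectorized; symmetric in `(ref, alt)`.
#'
#' @param ref,alt single bases in `{A,C,G,T}`, `ref != alt` elementwise.
#' @return A data.frame with columns `pair` (one of `"A/G" "C/T" "A/T"
#'   "A/C" "G/T" "G/C"`) and `class` (`"ts"` or `"tv"`).
#' @examples
#' classifyMutation(c("A", "T"), c("G", "C"))
#' @export
classifyMutation <- function(ref, alt) {
    ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
    bases <- c("A", "C", "G", "T")
    bad <- !(ref %in% bases) | !(alt %in% bases) | ref == alt
    if (any(bad))
        stop("invalid base pair(s): ",
             paste(unique(paste0(ref[bad], "/", alt[bad])), collapse = ", "))
    a <- pmin(ref, alt); b <- pmax(ref, alt)   # unordered, alphabetical
    key <- paste0(a, "/", b)
    canon <- c("A/G" = "A/G", "C/T" = "C/T", "A/T" = "A/T",
               "A/C" = "A/C", "G/T" = "G/T", "C/G" = "G/C")
    pair <- unname(canon[key])
    data.frame(pair = pair,
               class = ifelse(pair %in% c("A/G", "C/T"), "ts", "tv"))
}

.MUTATION_PAIRS <- c("A/G", "C/T", "A/T", "A/C", "G/T", "G/C")

#' Summarize mutation-type (ts/tv) composition
#'
#' Counts the six unordered substitution types and the derived
#' transition/transversion totals and fractions. Accepts either a
#' [VariantSites-class] stream (sites are classified from `ref`/`alt`) or a
#' named numeric vector of pre-tabulated counts with names among
#' `"A/G" "C/T" "A/T" "A/C" "G/T" "G/C"`.
#'
#' @param x a [VariantSites-class] or a named count vector.
#' @return An object of class `MutationTypeSummary`: a list with `counts`
#'   (the six types), `tsCount`, `tvCount`, `total`, `tsFraction`,
#'   `tvFraction`. Fractions are `NA` for an empty input. The print method
#'   reports percentages at one decimal.
#' @examples
#' summarizeMutationTypes(c("A/G" = 2, "A/T" = 1))
#' @export
summarizeMutationTypes <- function(x) {
    if (is(x, "VariantSites")) {
        cls <- if (length(x))
            classifyMutation(mcols(x)$ref, mcols(x)$alt)$pair
        else character()
        counts <- table(factor(cls, levels = .MUTATION_PAIRS))
        counts <- stats::setNames(as.numeric(counts), .MUTATION_PAIRS)
    } else {
        stopifnot(is.numeric(x), !is.null(names(x)))
        bad <- setdiff(names(x), .MUTATION_PAIRS)
        if (length(bad))
            stop("unknown mutation type(s): ", paste(bad, collapse = ", "))
        counts <- stats::setNames(rep(0, 6), .MUTATION_PAIRS)
        counts[names(x)] <- as.numeric(x)
    }
    tsCount <- sum(counts[c("A/G", "C/T")])
    tvCount <- sum(counts[c("A/T", "A/C", "G/T", "G/C")])
    total <- tsCount + tvCount
    out <- list(counts = counts, tsCount = tsCount, tvCount = tvCount,
                total = total,
                tsFraction = if (total > 0) tsCount / total else NA_real_,
                tvFraction = if (total > 0) tvCount / total else NA_real_)
    class(out) <- "MutationTypeSummary"
    out
}

#' @export
print.MutationTypeSummary <- function(x, ...) {
    cat("Mutation-type summary (", format(x$total, big.mark = ","),
        " sites)\n", sep = "")
    for (p in names(x$counts))
        cat(sprintf("  %-4s %s\n", p, format(x$counts[[p]], big.mark = ",")))
    if (is.na(x$tsFraction)) {
        cat("  ts/tv fractions undefined (no sites)\n")
    } else {
        cat(sprintf("  transitions   %.1f%%\n", 100 * x$tsFraction))
        cat(sprintf("  transversions %.1f%%\n", 100 * x$tvFraction))
    }
    invisible(x)
}

#' SNP counts per chromosome
#'
#' @param x a [VariantSites-class].
#' @return A data.frame with columns `chrom` and `n`, chromosomes in order
#'   of first appearance in the input.
#' @export
perChromosomeCounts <- function(x) {
    stopifnot(is(x, "VariantSites"))
    ch <- as.character(seqnames(x))
    lev <- unique(ch)
    tab <- table(factor(ch, levels = lev))
    data.frame(chrom = lev, n = as.integer(tab), row.names = NULL)
}
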