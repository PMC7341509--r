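## Per-site alt-allele frequency and called allele count for one sample
## group, from a "0/0" / "0/1" / "1/1" / "./." genotype matrix.
.alleleFreq <- function(gt) {
    called <- gt %in% c("0/0", "0/1", "1/1")
    altDose <- (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
    altDose[!called] <- 0L
    dim(altDose) <- dim(gt); dim(called) <- dim(gt)
    n <- 2L * rowSums(called)
    p <- ifelse(n > 0, rowSums(altDose) / n, NA_real_)
    list(p = p, n = n)
}

#' Per-site Fst numerator and denominator
#'
#' Computes the per-site components of the two-population Fst estimator so
#' that windows can combine sites as a ratio of sums. The default is
#' Hudson's estimator:
#' numerator \eqn{(p_1 - p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)},
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, with \eqn{p_i} the alt-allele
#' frequency and \eqn{n_i} the called allele count in group *i*. It is
#' robust at very small sample sizes (here 2 vs 6 diploids) and reaches
#' exactly 1 at a fixed difference. A Weir-Cockerham style
#' variance-component estimator on allele counts is available via
#' `estimator = "wc"`.
#'
#' Sites with fewer than 2 called alleles in either group return `NA`
#' components and are skipped by [windowFst()]. Monomorphic sites identical
#' in both groups have denominator 0 and contribute (0, 0).
#'
#' @param p1,p2 alt-allele frequencies in the two groups.
#' @param n1,n2 called allele counts (2 x called diploid genotypes).
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return A list with numeric vectors `num` and `den`.
#' @examples
#' fstSiteComponents(1, 4, 0, 12)  # fixed difference: num = den = 1
#' @export
fstSiteComponents <- function(p1, n1, p2, n2,
                              estimator = c("hudson", "wc")) {
    estimator <- match.arg(estimator)
    m <- max(length(p1), length(p2))
    p1 <- rep_len(p1, m); p2 <- rep_len(p2, m)
    n1 <- rep_len(n1, m); n2 <- rep_len(n2, m)
    ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
    num <- den <- rep(NA_real_, length(p1))
    if (estimator == "hudson") {
        num[ok] <- (p1[ok] - p2[ok])^2 -
            p1[ok] * (1 - p1[ok]) / (n1[ok] - 1) -
            p2[ok] * (1 - p2[ok]) / (n2[ok] - 1)
        den[ok] <- p1[ok] * (1 - p2[ok]) + p2[ok] * (1 - p1[ok])
    } else {
        ## Weir-Cockerham variance components on allele counts (r = 2 demes)
        nt <- n1 + n2
        pbar <- (n1 * p1 + n2 * p2) / nt
        MSP <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
        MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
        nc <- nt - (n1^2 + n2^2) / nt
        num[ok] <- (MSP - MSG)[ok]
        den[ok] <- (MSP + (nc - 1) * MSG)[ok]
    }
    list(num = num, den = den)
}

#' Windowed case/control Fst
#'
#' Tiles every chromosome with non-overlapping windows starting at
#' coordinate 1 (1-based inclusive ends, so a 150 kb window spans e.g.
#' 1-150000, 150001-300000, ...), assigns each SNP to its window, and
#' combines per-site estimator components as a ratio of sums:
#' window Fst = sum(numerators) / sum(denominators). Windows containing no
#' informative SNP are absent from the output; windows with fewer than
#' `minSnps` SNPs or a zero denominator sum are reported but flagged
#' `retained = FALSE` and excluded from the subsequent Z-transformation.
#'
#' @param x a [VariantSites-class], sorted by (chromosome, position).
#' @param split a [PopulationSplit-class]; all its samples must exist in `x`.
#' @param windowSize window span in bp (default 150000).
#' @param minSnps minimum informative SNPs for a window to enter the
#'   Z-transform (default 10).
#' @param estimator passed to [fstSiteComponents()].
#' @return A [GRanges] with metadata columns `nSnps`, `fst`, `retained`.
#' @export
windowFst <- function(x, split, windowSize = 150000L, minSnps = 10L,
                      estimator = c("hudson", "wc")) {
    stopifnot(is(x, "VariantSites"), is(split, "PopulationSplit"))
    estimator <- match.arg(estimator)
    samp <- colnames(x)
    unknown <- setdiff(c(caseSamples(split), controlSamples(split)), samp)
    if (length(unknown))
        stop("samples not in the VCF: ", paste(unknown, collapse = ", "))
    ch <- as.character(seqnames(x))
    if (length(x) > 1L) {
        blocks <- rle(ch)$values
        if (anyDuplicated(blocks) ||
            any(ch[-1] == ch[-length(ch)] & diff(start(x)) < 0))
            stop("variants must be sorted by (chromosome, position)")
    }
    gt <- mcols(x)$gt
    g1 <- .alleleFreq(gt[, caseSamples(split), drop = FALSE])
    g2 <- .alleleFreq(gt[, controlSamples(split), drop = FALSE])
    comp <- fstSiteComponents(g1$p, g1$n, g2$p, g2$n, estimator)
    ok <- !is.na(comp$num)
    widx <- (start(x) - 1) %/% windowSize
    key <- paste0(ch, ":", widx)[ok]
    if (!length(key)) {
        out <- GRanges()
        mcols(out) <- DataFrame(nSnps = integer(0), fst = numeric(0),
                                retained = logical(0))
        return(out)
    }
    lev <- unique(key)
    f <- factor(key, levels = lev)
    numSum <- as.numeric(rowsum(comp$num[ok], f))
    denSum <- as.numeric(rowsum(comp$den[ok], f))
    nSnps <- as.integer(table(f))
    parts <- matrix(unlist(strsplit(lev, ":", fixed = TRUE)), ncol = 2,
                    byrow = TRUE)
    wstart <- as.numeric(parts[, 2]) * windowSize + 1
    out <- GRanges(parts[, 1], IRanges(wstart, wstart + windowSize - 1))
    mcols(out) <- DataFrame(
        nSnps = nSnps,
        fst = ifelse(denSum > 0, numSum / denSum, NA_real_),
        retained = denSum > 0 & nSnps >= minSnps)
    out[order(match(as.character(seqnames(out)), unique(ch)), start(out))]
}

#' Z-transform window Fst and call sweep candidates
#'
#' Standardizes the Fst of retained windows to zero mean and unit variance
#' (sample standard deviation, n - 1) and flags as candidates all windows
#' whose ZFst reaches the empirical upper `topFraction` order-statistic
#' threshold: with *k* = `ceiling(topFraction * n)`, the threshold is the
#' *k*-th largest ZFst and every window at or above it (ties included) is a
#' candidate.
#'
#' @param windows output of [windowFst()].
#' @param topFraction upper tail fraction to call (default 0.01).
#' @return The retained windows as a [GRanges] with added `zfst` and
#'   `candidate` metadata columns.
#' @export
zFstCandidates <- function(windows, topFraction = 0.01) {
    w <- windows[mcols(windows)$retained]
    if (length(w) < 2L) stop("need >= 2 retained windows")
    fst <- mcols(w)$fst
    s <- stats::sd(fst)
    if (s == 0) stop("no variance across windows")
    z <- (fst - mean(fst)) / s
    k <- max(1L, ceiling(topFraction * length(z)))
    thr <- sort(z, decreasing = TRUE)[k]
    mcols(w)$zfst <- z
    mcols(w)$candidate <- z >= thr
    w
}

#' Genes overlapping candidate windows
#'
#' Reports, for each window, the annotation genes whose 1-based inclusive
#' intervals intersect the window by at least 1 bp.
#'
#' @param windows a [GRanges] of (candidate) windows.
#' @param genes a [GRanges] with a gene-name metadata column, or a BED/GFF3
#'   file path.
#' @return A data.frame with one row per (window, gene) overlap: `chrom`,
#'   `start`, `end`, `gene`. Windows without overlap are omitted.
#' @export
annotateWindows <- function(windows, genes) {
    genes <- .readGenes(genes)
    .checkSeqnames(windows, genes)
    ## .checkSeqnames already warned about disjoint chromosome sets
    hits <- suppressWarnings(
        findOverlaps(windows, genes, ignore.strand = TRUE))
    hits <- hits[order(S4Vectors::queryHits(hits),
                       S4Vectors::subjectHits(hits))]
    data.frame(
        chrom = as.character(seqnames(windows))[S4Vectors::queryHits(hits)],
        start = start(windows)[S4Vectors::queryHits(hits)],
        end = end(windows)[S4Vectors::queryHits(hits)],
        gene = mcols(genes)$gene[S4Vectors::subjectHits(hits)])
}
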