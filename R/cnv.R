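#' Read a sliding-window depth matrix from TSV
#'
#' Expects a header line `chrom  window_start  <sample1> .. <sampleN>` and
#' one row per window with 1-based window start coordinates.
#'
#' @param path TSV file path.
#' @param windowSize,step window span and stride in bp (defaults 800/400).
#' @return A [DepthWindowMatrix-class].
#' @export
readDepthWindows <- function(path, windowSize = 800L, step = 400L) {
    df <- utils::read.delim(path, check.names = FALSE)
    stopifnot(ncol(df) >= 3L)
    counts <- as.matrix(df[, -(1:2), drop = FALSE])
    windows <- GRanges(df[[1]], IRanges(df[[2]], width = windowSize))
    DepthWindowMatrix(counts, windows, windowSize, step)
}

#' Aggregate a per-base depth track onto sliding windows
#'
#' Sums per-base depth over each `windowSize`-bp window at `step`-bp stride
#' (windows tile each chromosome from position 1), producing the same
#' window read-count representation [readDepthWindows()] reads directly.
#'
#' @param track data.frame from [readDepthTrack()].
#' @param windowSize,step window span and stride in bp.
#' @return A [DepthWindowMatrix-class].
#' @export
depthTrackToWindows <- function(track, windowSize = 800L, step = 400L) {
    samples <- colnames(track)[-(1:2)]
    parts <- split(track, track[[1]])
    allCounts <- NULL; allGr <- GRanges()
    for (chrom in names(parts)) {
        p <- parts[[chrom]]
        L <- max(p[[2]])
        starts <- seq(1, max(1, L - windowSize + 1), by = step)
        cs <- apply(p[, samples, drop = FALSE], 2, function(d)
            cumsum(as.numeric(d)))
        ## cumulative sums indexed by position (positions assumed 1..L dense;
        ## missing positions contribute 0 via match)
        posIdx <- p[[2]]
        cumAt <- function(q) {  # cumulative depth up to position q
            i <- findInterval(q, posIdx)
            out <- matrix(0, length(q), length(samples))
            nz <- i >= 1L
            out[nz, ] <- cs[i[nz], , drop = FALSE]
            out
        }
        hi <- cumAt(starts + windowSize - 1)
        lo <- cumAt(starts - 1)
        counts <- matrix(as.integer(hi - lo), nrow = length(starts),
                         dimnames = list(NULL, samples))
        allCounts <- rbind(allCounts, counts)
        allGr <- c(allGr, GRanges(chrom, IRanges(starts, width = windowSize)))
    }
    DepthWindowMatrix(allCounts, allGr, windowSize, step)
}

#' Normalize window read counts to copy number
#'
#' Scales each sample's window counts by its genome-wide median so that the
#' typical (diploid) window sits at copy number 2:
#' `cn[w, s] = 2 * counts[w, s] / median_w(counts[, s])`. Optionally applies
#' a GC correction: with a per-window GC fraction supplied, windows are
#' binned into GC deciles and each sample's copy number is rescaled by the
#' bin's median so every decile re-centres at 2.
#'
#' @param x a [DepthWindowMatrix-class].
#' @param gc optional numeric vector of per-window GC fractions.
#' @return `x` with a `"copyNumber"` assay added.
#' @export
normalizeDepth <- function(x, gc = NULL) {
    stopifnot(is(x, "DepthWindowMatrix"))
    counts <- depthCounts(x)
    med <- apply(counts, 2, stats::median)
    zero <- med <= 0
    if (any(zero))
        stop("sample(s) with zero median depth: ",
             paste(colnames(counts)[zero], collapse = ", "))
    cn <- sweep(2 * counts, 2, med, "/")
    if (!is.null(gc)) {
        stopifnot(length(gc) == nrow(counts))
        bin <- cut(gc, stats::quantile(gc, seq(0, 1, 0.1)),
                   include.lowest = TRUE)
        for (s in seq_len(ncol(cn))) {
            m <- tapply(cn[, s], bin, stats::median)
            fac <- as.numeric(m[bin]) / 2
            fac[!is.finite(fac) | fac <= 0] <- 1
            cn[, s] <- cn[, s] / fac
        }
    }
    SummarizedExperiment::assay(x, "copyNumber", withDimnames = FALSE) <- cn
    x
}

#' Initial copy-number calls from extreme windows
#'
#' Flags each window in which any sample's normalized copy number reaches
#' the gain threshold (`>=`) or the loss threshold (`<=`), then reports
#' maximal runs of at least `minWindows` consecutive flagged windows
#' (consecutive = same chromosome, starts differing by the stride) as
#' initial calls spanning first-window start to last-window end.
#'
#' @param x a normalized [DepthWindowMatrix-class].
#' @param gainThreshold,lossThreshold copy-number cutoffs (defaults
#'   2.75 / 1.25, i.e. three-quarters of the way to the next integer state).
#' @param minWindows minimum run length (default 3).
#' @return A [GRanges] of initial call intervals.
#' @export
initialCalls <- function(x, gainThreshold = 2.75, lossThreshold = 1.25,
                         minWindows = 3L) {
    cn <- copyNumber(x)
    rr <- SummarizedExperiment::rowRanges(x)
    st <- metadata(x)$step
    flag <- rowSums(cn >= gainThreshold | cn <= lossThreshold) > 0
    ch <- as.character(seqnames(rr))
    ## break runs at chromosome changes and non-consecutive windows
    newBlock <- c(TRUE, ch[-1] != ch[-length(ch)] |
                        diff(start(rr)) != st)
    runId <- cumsum(newBlock | c(TRUE, diff(flag) != 0))
    keep <- which(flag)
    if (!length(keep)) return(GRanges())
    spl <- split(keep, runId[keep])
    spl <- spl[lengths(spl) >= minWindows]
    if (!length(spl)) return(GRanges())
    firsts <- vapply(spl, min, 0); lasts <- vapply(spl, max, 0)
    out <- GRanges(ch[firsts], IRanges(start(rr)[firsts], end(rr)[lasts]))
    sort(out)
}

## Per-sample mean normalized copy number over the windows contained in a
## region (windows whose span lies fully inside the region boundaries;
## call/region boundaries are themselves window boundaries).
.regionMeanCn <- function(region, x) {
    rr <- SummarizedExperiment::rowRanges(x)
    idx <- which(as.character(seqnames(rr)) == as.character(seqnames(region)) &
                 start(rr) >= start(region) & end(rr) <= end(region))
    if (!length(idx))   # degenerate: fall back to any overlap
        idx <- S4Vectors::queryHits(findOverlaps(rr, region))
    colMeans(copyNumber(x)[idx, , drop = FALSE])
}

#' Merge initial calls into CNV regions
#'
#' Adjacent same-chromosome calls are merged when (a) the gap between them
#' is strictly less than `maxGapFraction` of their combined length and (b)
#' the Pearson correlation across samples of the two calls' mean normalized
#' copy-number vectors is significant (two-sided test of r = 0) at
#' `corAlpha`. Merging is applied iteratively left-to-right until a fixed
#' point. With fewer than 3 samples the correlation test is impossible and
#' the distance rule alone decides, with a warning; the same fallback
#' applies to degenerate constant copy-number vectors.
#'
#' @param calls a [GRanges] of initial calls sorted by (chromosome, start).
#' @param x the normalized [DepthWindowMatrix-class] the calls came from.
#' @param maxGapFraction gap threshold as a fraction of the two calls'
#'   combined length (default 0.2, strict `<`).
#' @param corAlpha significance level of the correlation test (default 0.01).
#' @return A [CNVRegionSet-class] with per-sample mean copy number (`cn`).
#' @export
mergeCalls <- function(calls, x, maxGapFraction = 0.2, corAlpha = 0.01) {
    stopifnot(is(calls, "GRanges"))
    if (length(calls) && ncol(x) < 3L)
        warning("fewer than 3 samples: merge decided by distance alone")
    iv <- data.frame(chrom = as.character(seqnames(calls)),
                     start = start(calls), end = end(calls))
    iv <- iv[order(match(iv$chrom, unique(iv$chrom)), iv$start), ,
             drop = FALSE]
    meanCn <- function(row) .regionMeanCn(
        GRanges(row$chrom, IRanges(row$start, row$end)), x)
    repeat {
        merged <- FALSE
        i <- 1L
        while (i < nrow(iv)) {
            a <- iv[i, ]; b <- iv[i + 1L, ]
            if (a$chrom == b$chrom) {
                gap <- b$start - a$end - 1
                lenA <- a$end - a$start + 1; lenB <- b$end - b$start + 1
                if (gap < maxGapFraction * (lenA + lenB) &&
                    .cnCorrelated(meanCn(a), meanCn(b), corAlpha)) {
                    iv$end[i] <- max(a$end, b$end)
                    iv <- iv[-(i + 1L), , drop = FALSE]
                    merged <- TRUE
                    next    # retry at the same index with the grown region
                }
            }
            i <- i + 1L
        }
        if (!merged) break
    }
    regions <- GRanges(iv$chrom, IRanges(iv$start, iv$end))
    cn <- t(vapply(seq_len(nrow(iv)), function(i) meanCn(iv[i, ]),
                   numeric(ncol(x))))
    if (!nrow(iv)) cn <- matrix(numeric(0), 0, ncol(x))
    colnames(cn) <- colnames(x)
    mcols(regions) <- DataFrame(cn = I(cn))
    new("CNVRegionSet", regions)
}

## Correlation-significance rule shared by mergeCalls and its documentation:
## TRUE when the Pearson test of r = 0 across samples is significant, or
## when the test is impossible (< 3 samples, or a constant vector).
.cnCorrelated <- function(v1, v2, alpha) {
    if (length(v1) < 3L) return(TRUE)
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(TRUE)
    stats::cor.test(v1, v2)$p.value < alpha
}

## round half away from zero (2.5 -> 3), unlike R's banker's rounding
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer copy number and genotype codes per region
#'
#' Rounds each sample's mean normalized copy number to an integer
#' (half-away-from-zero, so an estimate of exactly 2.5 becomes 3 copies)
#' and maps it to the genotype code used for CNV reporting: 0 copies `D`,
#' 1 `Ad`, 2 `AA` (diploid normal), 3 `AB`, 4 `BB`, 5 or more `M`.
#'
#' @param regions a [CNVRegionSet-class].
#' @return `regions` with `cnInteger` and `genotype` matrix columns added.
#' @export
genotypeRegions <- function(regions) {
    stopifnot(is(regions, "CNVRegionSet"))
    cn <- mcols(regions)$cn
    cnInt <- .roundHalfAway(cn)
    codes <- c("D", "Ad", "AA", "AB", "BB")
    geno <- ifelse(cnInt >= 5, "M", codes[pmin(cnInt, 4) + 1L])
    dim(geno) <- dim(cn); dimnames(geno) <- dimnames(cn)
    storage.mode(cnInt) <- "integer"
    mcols(regions)$cnInteger <- I(cnInt)
    mcols(regions)$genotype <- I(geno)
    regions
}

#' The Vst population-differentiation statistic
#'
#' Vst = (Vt - Vs) / Vt, where Vt is the population variance (divide by N)
#' of all samples' per-region values and Vs the size-weighted mean of the
#' within-group population variances, `(n1 V1 + n2 V2) / N`. With this
#' weighting the law of total variance guarantees Vt >= Vs, hence
#' Vst in the unit interval. An unweighted variant, `Vs = (V1 + V2) / 2`, is available
#' but can leave the unit interval for unbalanced groups. Returns 0 when
#' Vt = 0 (all samples identical).
#'
#' @param caseValues,controlValues numeric per-sample region values
#'   (typically mean log2 copy-number ratios).
#' @param weighted use size-weighted within-group variances (default TRUE).
#' @return Vst as a single numeric.
#' @examples
#' vstStatistic(c(1, 1), c(0, 0, 0, 0))     # 1: groups internally identical
#' @export
vstStatistic <- function(caseValues, controlValues, weighted = TRUE) {
    n1 <- length(caseValues); n2 <- length(controlValues)
    if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
    all <- c(caseValues, controlValues)
    popVar <- function(v) mean((v - mean(v))^2)
    vt <- popVar(all)
    if (vt == 0) return(0)
    vs <- if (weighted)
        (n1 * popVar(caseValues) + n2 * popVar(controlValues)) / (n1 + n2)
    else
        (popVar(caseValues) + popVar(controlValues)) / 2
    (vt - vs) / vt
}

#' Per-region Vst from window copy number
#'
#' For each region, computes every sample's mean log2 copy-number ratio,
#' `mean over region windows of log2(cn / 2)` with `cn` floored at
#' `floorCn` before the log (so homozygous deletions stay finite), then
#' applies [vstStatistic()] between the split's groups.
#'
#' @param regions a [CNVRegionSet-class].
#' @param x the normalized [DepthWindowMatrix-class].
#' @param split a [PopulationSplit-class].
#' @param floorCn lower floor applied to copy number before the log
#'   (default 0.05).
#' @param weighted passed to [vstStatistic()].
#' @return `regions` with `meanLog2` matrix and `vst` numeric columns added.
#' @export
regionVst <- function(regions, x, split, floorCn = 0.05, weighted = TRUE) {
    stopifnot(is(regions, "CNVRegionSet"), is(split, "PopulationSplit"))
    rr <- SummarizedExperiment::rowRanges(x)
    cn <- copyNumber(x)
    lg <- log2(pmax(cn, floorCn) / 2)
    ml <- t(vapply(seq_along(regions), function(i) {
        idx <- which(as.character(seqnames(rr)) ==
                         as.character(seqnames(regions))[i] &
                     start(rr) >= start(regions)[i] &
                     end(rr) <= end(regions)[i])
        if (!length(idx))
            idx <- S4Vectors::queryHits(findOverlaps(rr, regions[i]))
        colMeans(lg[idx, , drop = FALSE])
    }, numeric(ncol(x))))
    if (!length(regions)) ml <- matrix(numeric(0), 0, ncol(x))
    colnames(ml) <- colnames(x)
    v <- vapply(seq_along(regions), function(i)
        vstStatistic(ml[i, caseSamples(split)],
                     ml[i, controlSamples(split)], weighted), 0)
    mcols(regions)$meanLog2 <- I(ml)
    mcols(regions)$vst <- as.numeric(v)
    regions
}

#' Filter candidate CNV regions
#'
#' Retains regions with length strictly greater than `minLength` and Vst
#' strictly greater than `minVst`. By default regions on the X chromosome
#' and on unplaced scaffolds (chromosome names not of the form
#' `chr<number>` or `<number>`) are excluded from candidate reporting;
#' set `autosomesOnly = FALSE` to keep them.
#'
#' @param regions a [CNVRegionSet-class] with `vst` computed.
#' @param minLength,minVst strict lower cutoffs (defaults 2000 bp, 0.25).
#' @param autosomesOnly drop X/scaffold regions (default TRUE).
#' @return The filtered [CNVRegionSet-class].
#' @export
filterCandidates <- function(regions, minLength = 2000, minVst = 0.25,
                             autosomesOnly = TRUE) {
    v <- vstValues(regions)
    keep <- width(regions) > minLength & !is.na(v) & v > minVst
    if (autosomesOnly)
        keep <- keep & grepl("^(chr)?[0-9]+$",
                             as.character(seqnames(regions)))
    regions[keep]
}

#' Nearest or overlapping gene per CNV region
#'
#' For each region, reports every overlapping gene at distance 0; regions
#' without overlap get their nearest gene with the gap in nt and an
#' orientation label: `downstream` when the gene starts after the region
#' end (distance = gene start - region end), `upstream` when the gene ends
#' before the region start (distance = region start - gene end). Regions on
#' chromosomes absent from the annotation (or an empty annotation) are
#' reported `intergenic` with `NA` distance.
#'
#' @param regions a [CNVRegionSet-class] or [GRanges].
#' @param genes a [GRanges] with gene names, or a BED/GFF3 path.
#' @return A data.frame: `chrom`, `start`, `end`, `gene`, `distance`,
#'   `orientation` (one row per overlap, or one row per region otherwise).
#' @export
annotateRegions <- function(regions, genes) {
    genes <- .readGenes(genes)
    out <- NULL
    for (i in seq_along(regions)) {
        ch <- as.character(seqnames(regions))[i]
        s <- start(regions)[i]; e <- end(regions)[i]
        g <- genes[as.character(seqnames(genes)) == ch]
        row <- function(gene, d, o) data.frame(chrom = ch, start = s,
            end = e, gene = gene, distance = d, orientation = o)
        if (!length(g)) { out <- rbind(out, row(NA, NA, "intergenic")); next }
        ov <- start(g) <= e & end(g) >= s
        if (any(ov)) {
            out <- rbind(out, row(mcols(g)$gene[ov], 0, "overlap"))
        } else {
            dDown <- ifelse(start(g) > e, start(g) - e, Inf)
            dUp <- ifelse(end(g) < s, s - end(g), Inf)
            d <- pmin(dDown, dUp)
            j <- which.min(d)
            out <- rbind(out, row(mcols(g)$gene[j], d[j],
                                  if (dDown[j] <= dUp[j]) "downstream"
                                  else "upstream"))
        }
    }
    if (is.null(out))
        out <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), gene = character(),
                          distance = numeric(), orientation = character())
    out
}
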