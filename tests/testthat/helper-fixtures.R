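## In-code fixtures shared across test files.

## Construct a VariantSites object directly from vectors.
makeSites <- function(chrom, pos, ref, alt, qual = 60, depth = 30,
                      gt = NULL, samples = c("case1", "case2",
                                             paste0("ctrl", 1:6))) {
    n <- length(pos)
    if (is.null(gt))
        gt <- matrix("0/1", n, length(samples),
                     dimnames = list(NULL, samples))
    gr <- GenomicRanges::GRanges(rep_len(chrom, n),
        IRanges::IRanges(pos, pos))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = rep_len(ref, n), alt = rep_len(alt, n),
        qual = rep_len(qual, n), depth = rep_len(depth, n), gt = I(gt))
    new("VariantSites", gr)
}

## A DepthWindowMatrix whose normalized copy number equals a given matrix:
## counts are cn * 50 and the per-sample median is forced to 100 by
## padding with diploid windows (cn 2 -> counts 100).
makeDwmFromCn <- function(cn, chrom = "chr1", pad = max(20L, nrow(cn)),
                          windowSize = 800L, step = 400L) {
    samples <- colnames(cn)
    if (is.null(samples)) {
        samples <- sprintf("s%d", seq_len(ncol(cn)))
        colnames(cn) <- samples
    }
    full <- rbind(matrix(2, pad, ncol(cn)), cn,
                  matrix(2, pad, ncol(cn)))
    counts <- full * 50
    starts <- seq(1, by = step, length.out = nrow(full))
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(starts, width = windowSize))
    colnames(counts) <- samples
    dwm <- DepthWindowMatrix(counts, gr, windowSize, step)
    normalizeDepth(dwm)
}

## Default population split matching the simulator's sample naming.
defaultSplit <- function(nCases = 2, nControls = 6)
    PopulationSplit(sprintf("case%d", seq_len(nCases)),
                    sprintf("ctrl%d", seq_len(nControls)))

## Quiet wrapper: simulate a cohort and read its VCF back.
simulateAndRead <- function(config, dir = tempfile("fix")) {
    out <- simulateCohort(config, dir)
    out$variants <- suppressMessages(readBiallelicVariants(out$vcf))
    out
}
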