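#' Read a per-base depth track (samtools-depth layout)
#'
#' Reads a headerless TSV with columns `chrom  pos  depth_1 .. depth_N`,
#' the layout `samtools depth` prints for N samples.
#'
#' @param path TSV file path.
#' @param sampleNames optional character vector naming the depth columns;
#'   defaults to `sample1..sampleN`.
#' @return A data.frame with columns `chrom`, `pos` and one depth column
#'   per sample.
#' @export
readDepthTrack <- function(path, sampleNames = NULL) {
    df <- utils::read.delim(path, header = FALSE)
    stopifnot(ncol(df) >= 3L)
    n <- ncol(df) - 2L
    if (is.null(sampleNames)) sampleNames <- sprintf("sample%d", seq_len(n))
    stopifnot(length(sampleNames) == n)
    colnames(df) <- c("chrom", "pos", sampleNames)
    df
}

#' Normalized per-base depth profile over a target region
#'
#' Divides each sample's per-base depth inside the region by that sample's
#' genome-wide mean depth, computed from the track excluding the queried
#' region itself (so a true deletion does not dilute its own baseline on a
#' small genome). Positions absent from the track read as depth 0; the
#' profile always has one row per base of the region.
#'
#' @param track data.frame from [readDepthTrack()].
#' @param region a [GRanges] of length 1 or a `"chrom:start-end"` string.
#' @return A list with `profile` (region-length x samples matrix of
#'   normalized depth), `meanRawDepth` and `genomeMeanDepth` (per-sample
#'   vectors) and `region`.
#' @export
regionDepthProfile <- function(track, region) {
    region <- .asRegion(region)
    chrom <- as.character(seqnames(region))
    if (!chrom %in% unique(track$chrom))
        stop("region chromosome '", chrom, "' not present in the depth track")
    samples <- colnames(track)[-(1:2)]
    inRegion <- track$chrom == chrom &
                track$pos >= start(region) & track$pos <= end(region)
    bg <- track[!inRegion, samples, drop = FALSE]
    if (!nrow(bg)) bg <- track[, samples, drop = FALSE]
    genomeMean <- colMeans(bg)
    if (any(genomeMean <= 0))
        stop("zero genome-wide mean depth for sample(s): ",
             paste(samples[genomeMean <= 0], collapse = ", "))
    pos <- seq(start(region), end(region))
    hit <- match(pos, track$pos[inRegion])
    profile <- matrix(0, length(pos), length(samples),
                      dimnames = list(NULL, samples))
    found <- !is.na(hit)
    profile[found, ] <- as.matrix(
        track[inRegion, samples, drop = FALSE])[hit[found], , drop = FALSE]
    list(profile = sweep(profile, 2, genomeMean, "/"),
         meanRawDepth = colMeans(profile),
         genomeMeanDepth = genomeMean, region = region)
}

#' Presence/absence verdict per sample
#'
#' Classifies each sample from its mean normalized depth ratio over the
#' region: ratio below `absentThreshold` (the operational reading of
#' "read depth essentially zero") is `absent`; ratio in
#' `[absentThreshold, hetThreshold)` is `heterozygous_loss` (one of two
#' copies missing sits near 0.5); anything at or above `hetThreshold` is
#' `present`. Verdicts are monotone in the ratio.
#'
#' @param profile a normalized base x sample matrix, or the list returned
#'   by [regionDepthProfile()].
#' @param absentThreshold,hetThreshold ratio cutoffs, `0 <
#'   absentThreshold < hetThreshold < 1` (defaults 0.05 / 0.75).
#' @return A data.frame (`RegionPresenceReport`): `sample`,
#'   `meanRawDepth`, `genomeMeanDepth`, `normalizedRatio`, `verdict`.
#' @export
presenceVerdict <- function(profile, absentThreshold = 0.05,
                            hetThreshold = 0.75) {
    stopifnot(absentThreshold > 0, absentThreshold < hetThreshold,
              hetThreshold < 1)
    meanRaw <- genomeMean <- NULL
    if (is.list(profile) && !is.null(profile$profile)) {
        meanRaw <- profile$meanRawDepth
        genomeMean <- profile$genomeMeanDepth
        profile <- profile$profile
    }
    if (!nrow(profile)) stop("empty depth profile")
    ratio <- colMeans(profile)
    verdict <- ifelse(ratio < absentThreshold, "absent",
               ifelse(ratio < hetThreshold, "heterozygous_loss", "present"))
    data.frame(sample = colnames(profile),
               meanRawDepth = if (is.null(meanRaw)) NA_real_ else
                   as.numeric(meanRaw),
               genomeMeanDepth = if (is.null(genomeMean)) NA_real_ else
                   as.numeric(genomeMean),
               normalizedRatio = as.numeric(ratio),
               verdict = verdict, row.names = NULL)
}

#' One-call region presence test
#'
#' Convenience wrapper: [regionDepthProfile()] followed by
#' [presenceVerdict()].
#'
#' @inheritParams regionDepthProfile
#' @inheritParams presenceVerdict
#' @return The per-sample presence report data.frame.
#' @export
regionPresence <- function(track, region, absentThreshold = 0.05,
                           hetThreshold = 0.75) {
    presenceVerdict(regionDepthProfile(track, region),
                    absentThreshold, hetThreshold)
}
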