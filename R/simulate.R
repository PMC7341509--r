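#' Simulate a ground-truth-labelled case-control cohort
#'
#' Generates the three inputs every downstream stage consumes: a minimal
#' VCFv4.2 with diploid genotypes for all samples, a sliding-window
#' read-count matrix (TSV), and a [GroundTruth-class] record of the planted
#' features (also written as JSON).
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium within group at
#' independent sites: outside planted sweep intervals both groups share a
#' Beta-distributed baseline allele frequency; inside a planted sweep the
#' groups use the interval's `caseFreq` / `controlFreq`. Window read counts
#' are Poisson with mean `meanDepth * CN / 2`, where the true copy number CN
#' is 2 everywhere except inside planted CNV intervals (windows fully
#' contained in the interval take the group's planted copy number).
#'
#' Identical `(config, seed)` pairs reproduce byte-identical files; each
#' output draws from its own deterministically derived random stream, so
#' e.g. adding a planted CNV does not perturb the simulated genotypes.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with elements `vcf`, `depth`, `truthJson`
#'   (file paths) and `truth` (the [GroundTruth-class] object).
#' @seealso [simulateDeletionTrack()], [simulateGeneAnnotation()]
#' @export
simulateCohort <- function(config, dir = tempfile("cohort")) {
    validObject(config)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    samples <- c(sprintf("case%d", seq_len(config@nCases)),
                 sprintf("ctrl%d", seq_len(config@nControls)))
    isCase <- seq_along(samples) <= config@nCases
    chroms <- sprintf("chr%d", seq_len(config@nChromosomes))
    L <- config@chromosomeLength

    ## ---- VCF -------------------------------------------------------------
    set.seed(.subSeed(config@seed, "snp"))
    bases <- c("A", "C", "G", "T")
    vcfPath <- file.path(dir, "cohort.vcf")
    con <- file(vcfPath, "w")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=SweepCNV-simulateCohort",
        sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(L)),
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site read depth\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t")), con)
    gtCodes <- c("0/0", "0/1", "1/1")
    for (chrom in chroms) {
        nSnp <- round(L * config@snpDensity)
        if (nSnp == 0L) next
        pos <- sort(sample.int(L, nSnp))
        p0 <- stats::rbeta(nSnp, config@betaShape1, config@betaShape2)
        pCase <- pCtrl <- p0
        sw <- config@sweeps
        if (nrow(sw)) for (i in which(sw$chrom == chrom)) {
            in.iv <- pos >= sw$start[i] & pos <= sw$end[i]
            pCase[in.iv] <- sw$caseFreq[i]
            pCtrl[in.iv] <- sw$controlFreq[i]
        }
        ref <- sample(bases, nSnp, replace = TRUE)
        ## alt: transition partner with prob tsProbability, else one of the
        ## two transversion partners
        isTs <- stats::runif(nSnp) < config@tsProbability
        tsPartner <- c(A = "G", C = "T", G = "A", T = "C")
        tvPartners <- rbind(c("C", "T"), c("A", "G"),
                            c("C", "T"), c("A", "G"))   # rows follow bases
        alt <- ifelse(isTs, tsPartner[ref],
                      tvPartners[cbind(match(ref, bases),
                                       sample.int(2L, nSnp, replace = TRUE))])
        gt <- matrix("", nSnp, length(samples))
        for (s in seq_along(samples)) {
            p <- if (isCase[s]) pCase else pCtrl
            gt[, s] <- gtCodes[stats::rbinom(nSnp, 2L, p) + 1L]
        }
        qual <- rep(60L, nSnp)
        nLow <- floor(config@lowQualFraction * nSnp)
        if (nLow > 0L) qual[sample.int(nSnp, nLow)] <- 10L
        dp <- stats::rpois(nSnp, 30)
        lines <- paste(chrom, pos, ".", ref, alt, qual, "PASS",
                       paste0("DP=", dp), "GT",
                       apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
        writeLines(lines, con)
    }
    close(con)

    ## ---- depth window matrix ---------------------------------------------
    set.seed(.subSeed(config@seed, "depth"))
    ws <- 800L; st <- 400L
    depthPath <- file.path(dir, "depth_windows.tsv")
    allStarts <- seq(1, L - ws + 1, by = st)
    dcon <- file(depthPath, "w")
    writeLines(paste(c("chrom", "window_start", samples), collapse = "\t"),
               dcon)
    for (chrom in chroms) {
        cnCase <- rep(2, length(allStarts))
        cnCtrl <- rep(2, length(allStarts))
        cv <- config@cnvs
        if (nrow(cv)) for (i in which(cv$chrom == chrom)) {
            contained <- allStarts >= cv$start[i] &
                         allStarts + ws - 1 <= cv$end[i]
            cnCase[contained] <- cv$caseCN[i]
            cnCtrl[contained] <- cv$controlCN[i]
        }
        counts <- matrix(0L, length(allStarts), length(samples))
        for (s in seq_along(samples)) {
            cn <- if (isCase[s]) cnCase else cnCtrl
            counts[, s] <- stats::rpois(length(allStarts),
                                        config@meanDepth * cn / 2)
        }
        utils::write.table(
            data.frame(chrom, allStarts, counts),
            dcon, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    }
    close(dcon)

    ## ---- ground truth ----------------------------------------------------
    sw <- config@sweeps; cv <- config@cnvs; del <- config@deletion
    gr <- function(df) if (nrow(df)) GRanges(df$chrom,
        IRanges(df$start, df$end)) else GRanges()
    sweeps <- gr(sw)
    if (length(sweeps)) mcols(sweeps) <- DataFrame(
        caseFreq = sw$caseFreq, controlFreq = sw$controlFreq)
    cnvs <- gr(cv)
    if (length(cnvs)) mcols(cnvs) <- DataFrame(
        caseCN = as.integer(cv$caseCN), controlCN = as.integer(cv$controlCN))
    delGr <- GRanges()
    if (length(del)) {
        delGr <- GRanges(del$chrom, IRanges(del$start, del$end))
        mcols(delGr) <- DataFrame(
            samples = paste(del$samples, collapse = ","),
            residualFraction = del$residualFraction)
    }
    truth <- new("GroundTruth", sweeps = sweeps, cnvs = cnvs,
                 deletion = delGr,
                 caseSamples = samples[isCase],
                 controlSamples = samples[!isCase])
    truthJson <- file.path(dir, "ground_truth.json")
    asList <- function(g) if (!length(g)) list() else
        cbind(data.frame(chrom = as.character(seqnames(g)),
                         start = start(g), end = end(g)),
              as.data.frame(mcols(g)))
    jsonlite::write_json(list(
        caseSamples = truth@caseSamples,
        controlSamples = truth@controlSamples,
        sweeps = asList(sweeps), cnvs = asList(cnvs),
        deletion = asList(delGr)), truthJson,
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(vcf = vcfPath, depth = depthPath,
                   truthJson = truthJson, truth = truth))
}

#' Simulate a per-base depth track around a planted deletion
#'
#' Writes a samtools-depth style TSV (`chrom  pos  depth_sample1..N`, no
#' header) covering the configured deletion interval plus `flank` bp of
#' background on each side, the regional extract `samtools depth -r`
#' would produce. Unaffected samples (and all samples outside the interval) draw
#' per-base depth Poisson with mean `baseDepth`; affected samples draw
#' Poisson with mean `residualFraction * baseDepth` inside the interval
#' (residual 0 gives exact zeros).
#'
#' @param config a [SimulationConfig-class] with a planted deletion.
#' @param file output TSV path.
#' @param baseDepth mean per-base read depth per sample; the default 20
#'   matches typical medium-coverage resequencing.
#' @param flank bp of unaffected background emitted on each side of the
#'   interval (clipped at the chromosome ends).
#' @return Invisibly, a list with `file`, `samples` and the deletion
#'   interval as a [GRanges].
#' @export
simulateDeletionTrack <- function(config, file = tempfile(fileext = ".tsv"),
                                  baseDepth = 20, flank = 20000) {
    validObject(config)
    del <- config@deletion
    if (!length(del)) stop("config has no planted deletion")
    samples <- c(sprintf("case%d", seq_len(config@nCases)),
                 sprintf("ctrl%d", seq_len(config@nControls)))
    bad <- setdiff(del$samples, samples)
    if (length(bad))
        stop("deletion names unknown samples: ", paste(bad, collapse = ", "))
    set.seed(.subSeed(config@seed, "track"))
    L <- as.integer(config@chromosomeLength)
    pos <- seq(max(1, del$start - flank), min(L, del$end + flank))
    inside <- pos >= del$start & pos <= del$end
    depth <- matrix(0L, length(pos), length(samples),
                    dimnames = list(NULL, samples))
    for (s in samples) {
        mu <- rep(baseDepth, length(pos))
        if (s %in% del$samples) mu[inside] <- del$residualFraction * baseDepth
        depth[, s] <- stats::rpois(length(pos), mu)
    }
    utils::write.table(data.frame(del$chrom, pos, depth),
                       file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(list(file = file, samples = samples,
                   region = GRanges(del$chrom, IRanges(del$start, del$end))))
}

#' Deterministic synthetic gene annotation for a simulated genome
#'
#' Tiles genes of fixed length at a fixed spacing along every simulated
#' chromosome, so that planted sweep/CNV intervals have known overlapping or
#' nearest genes. Purely deterministic (no random draws).
#'
#' @param config a [SimulationConfig-class].
#' @param geneLength,spacing gene span and start-to-start distance in bp.
#' @return A [GRanges] with a `gene` metadata column.
#' @export
simulateGeneAnnotation <- function(config, geneLength = 2000L,
                                   spacing = 50000L) {
    L <- config@chromosomeLength
    chroms <- sprintf("chr%d", seq_len(config@nChromosomes))
    starts <- seq(spacing / 2, L - geneLength, by = spacing)
    if (!length(starts)) stop("chromosome too short for any gene")
    gr <- GRanges(rep(chroms, each = length(starts)),
                  IRanges(rep(starts, length(chroms)), width = geneLength))
    mcols(gr)$gene <- sprintf("%s_g%03d", rep(chroms, each = length(starts)),
                              rep(seq_along(starts), length(chroms)))
    gr
}

#' Random term-to-gene map for enrichment testing
#'
#' Draws `nTerms` gene sets of size `termSize` uniformly (without
#' replacement within a term) from a gene universe.
#'
#' @param genes character vector of gene identifiers (the background), or a
#'   [GRanges] from [simulateGeneAnnotation()].
#' @param nTerms,termSize number and size of terms; `termSize` is capped
#'   at the universe size.
#' @param seed integer seed.
#' @return A named list of character vectors (term id to gene set), with the
#'   universe attached as `attr(, "background")`.
#' @export
simulateTermMap <- function(genes, nTerms = 40L, termSize = 25L, seed = 1L) {
    if (is(genes, "GRanges")) genes <- mcols(genes)$gene
    genes <- unique(as.character(genes))
    termSize <- min(termSize, length(genes))
    set.seed(.subSeed(seed, "terms"))
    tm <- lapply(seq_len(nTerms),
                 function(i) sample(genes, termSize))
    names(tm) <- sprintf("TERM%04d", seq_len(nTerms))
    attr(tm, "background") <- genes
    tm
}
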