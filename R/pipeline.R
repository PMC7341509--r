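.pipelineDefaults <- function() list(
    seed = 1L,
    simulation = list(
        nChromosomes = 2L, chromosomeLength = 6e5, nCases = 2L,
        nControls = 6L, snpDensity = 1e-3, betaShape1 = 0.8,
        betaShape2 = 0.8, sweeps = NULL, cnvs = NULL, deletion = NULL,
        meanDepth = 100, lowQualFraction = 0),
    snp = list(minDepth = 4, minQual = 20),
    sweep = list(windowSize = 150000L, topFraction = 0.01, minSnps = 10L,
                 estimator = "hudson"),
    cnv = list(gainThreshold = 2.75, lossThreshold = 1.25, minWindows = 3L,
               maxGapFraction = 0.2, corAlpha = 0.01, minLength = 2000,
               minVst = 0.25, autosomesOnly = TRUE, floorCn = 0.05),
    presence = list(absentThreshold = 0.05, hetThreshold = 0.75,
                    baseDepth = 20),
    enrichment = list(nTerms = 40L, termSize = 25L),
    annotation = list(geneLength = 2000L, spacing = 50000L))

## Merge user config into defaults, rejecting unknown keys at the top and
## stage levels (planted-feature tables inside `simulation` are data, not
## keys, and are replaced wholesale).
.mergeConfig <- function(user, defaults = .pipelineDefaults()) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(user)) {
        if (is.list(defaults[[k]]) && k != "simulation") {
            bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
            if (length(bad))
                stop("unknown config key(s) under '", k, "': ",
                     paste(bad, collapse = ", "))
            defaults[[k]][names(user[[k]])] <- user[[k]]
        } else if (k == "simulation") {
            bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
            if (length(bad))
                stop("unknown config key(s) under 'simulation': ",
                     paste(bad, collapse = ", "))
            defaults[[k]][names(user[[k]])] <- user[[k]]
        } else defaults[[k]] <- user[[k]]
    }
    defaults
}

#' Run the full synthetic-study pipeline
#'
#' One call that replicates the whole analysis on a simulated cohort:
#' simulate (VCF + depth windows + optional deletion track + gene
#' annotation + term map), SNP filtering and mutation-type accounting,
#' windowed ZFst sweep scan with gene annotation, depth CNV calling with
#' merging, genotyping, Vst and filtering, the region presence test on the
#' planted deletion, and gene-set enrichment of the sweep-candidate genes.
#' Every stage writes its table under `outDir`; a machine-readable
#' `summary.json` and the fully resolved configuration
#' (`config_resolved.yaml`) are written last. Re-running with the same
#' config and seed reproduces the outputs byte-identically.
#'
#' @param config a (possibly partial) configuration list, or a path to a
#'   YAML/JSON file with the same structure. Unknown keys are rejected.
#'   Top-level keys: `seed`, `simulation`, `snp`, `sweep`, `cnv`,
#'   `presence`, `enrichment`, `annotation`.
#' @param outDir output directory (created; stage files inside).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("run")) {
    if (is.character(config) && length(config) == 1L) {
        config <- if (tolower(tools::file_ext(config)) == "json")
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    toDf <- function(x) if (is.null(x) || is.data.frame(x)) x else
        as.data.frame(x, stringsAsFactors = FALSE)
    config$simulation$sweeps <- toDf(config$simulation$sweeps)
    config$simulation$cnvs <- toDf(config$simulation$cnvs)
    cfg <- .mergeConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    sim <- cfg$simulation
    scfg <- SimulationConfig(
        nChromosomes = sim$nChromosomes,
        chromosomeLength = sim$chromosomeLength, nCases = sim$nCases,
        nControls = sim$nControls, snpDensity = sim$snpDensity,
        betaShape1 = sim$betaShape1, betaShape2 = sim$betaShape2,
        sweeps = sim$sweeps, cnvs = sim$cnvs, deletion = sim$deletion,
        meanDepth = sim$meanDepth, lowQualFraction = sim$lowQualFraction,
        seed = cfg$seed)
    inputs <- simulateCohort(scfg, file.path(outDir, "inputs"))
    truth <- inputs$truth
    split <- PopulationSplit(truth@caseSamples, truth@controlSamples)
    genes <- simulateGeneAnnotation(scfg, cfg$annotation$geneLength,
                                    cfg$annotation$spacing)

    ## ---- SNP statistics --------------------------------------------------
    variants <- readBiallelicVariants(inputs$vcf)
    kept <- filterSites(variants, cfg$snp$minDepth, cfg$snp$minQual)
    mts <- summarizeMutationTypes(kept)
    chromCounts <- perChromosomeCounts(kept)
    utils::write.table(chromCounts,
        file.path(outDir, "snp_per_chromosome.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- sweep scan ------------------------------------------------------
    wf <- windowFst(kept, split, cfg$sweep$windowSize, cfg$sweep$minSnps,
                    cfg$sweep$estimator)
    zw <- zFstCandidates(wf, cfg$sweep$topFraction)
    windowTab <- data.frame(chrom = as.character(seqnames(zw)),
        start = start(zw), end = end(zw), nSnps = mcols(zw)$nSnps,
        fst = mcols(zw)$fst, zfst = mcols(zw)$zfst,
        candidate = mcols(zw)$candidate)
    utils::write.table(windowTab, file.path(outDir, "sweep_windows.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    cand <- zw[mcols(zw)$candidate]
    sweepGenes <- annotateWindows(cand, genes)
    utils::write.table(sweepGenes, file.path(outDir, "sweep_genes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- CNV / Vst -------------------------------------------------------
    dwm <- normalizeDepth(readDepthWindows(inputs$depth))
    calls <- initialCalls(dwm, cfg$cnv$gainThreshold, cfg$cnv$lossThreshold,
                          cfg$cnv$minWindows)
    regions <- mergeCalls(calls, dwm, cfg$cnv$maxGapFraction,
                          cfg$cnv$corAlpha)
    regions <- genotypeRegions(regions)
    regions <- regionVst(regions, dwm, split, cfg$cnv$floorCn)
    cnvr <- filterCandidates(regions, cfg$cnv$minLength, cfg$cnv$minVst,
                             cfg$cnv$autosomesOnly)
    cnvAnno <- annotateRegions(cnvr, genes)
    cnvrTab <- data.frame(chrom = as.character(seqnames(cnvr)),
        start = start(cnvr), end = end(cnvr), length = width(cnvr),
        vst = vstValues(cnvr))
    if (length(cnvr)) {
        gdf <- as.data.frame(unclass(genotypeCodes(cnvr)))
        colnames(gdf) <- paste0("geno_", colnames(genotypeCodes(cnvr)))
        cnvrTab <- cbind(cnvrTab, gdf)
    }
    utils::write.table(cnvrTab, file.path(outDir, "cnv_regions.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cnvAnno, file.path(outDir, "cnv_genes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- region presence -------------------------------------------------
    presence <- NULL
    if (length(truth@deletion)) {
        tr <- simulateDeletionTrack(scfg,
            file.path(outDir, "inputs", "deletion_track.tsv"),
            cfg$presence$baseDepth)
        track <- readDepthTrack(tr$file, tr$samples)
        presence <- regionPresence(track, tr$region,
            cfg$presence$absentThreshold, cfg$presence$hetThreshold)
        utils::write.table(presence,
            file.path(outDir, "region_presence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    ## ---- enrichment ------------------------------------------------------
    termMap <- simulateTermMap(genes, cfg$enrichment$nTerms,
                               cfg$enrichment$termSize, cfg$seed)
    enr <- NULL
    query <- unique(sweepGenes$gene)
    if (length(query)) {
        enr <- hypergeometricEnrichment(query, termMap)
        utils::write.table(enr, file.path(outDir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    ## ---- summary + resolved config --------------------------------------
    summary <- list(
        seed = cfg$seed,
        samples = list(cases = truth@caseSamples,
                       controls = truth@controlSamples),
        snp = list(total = mts$total,
                   tsFraction = mts$tsFraction,
                   tvFraction = mts$tvFraction),
        sweep = list(windows = length(zw),
                     candidates = sum(mcols(zw)$candidate),
                     candidateGenes = sort(unique(sweepGenes$gene))),
        cnv = list(initialCalls = length(calls),
                   regions = length(regions),
                   candidates = cnvrTab),
        presence = presence,
        enrichment = if (is.null(enr)) NULL else
            list(tested = nrow(enr),
                 significant = sum(enr$significant),
                 significantFDR = sum(enr$significantFDR)))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    cfgOut <- cfg
    cfgOut$simulation$sweeps <- if (is.null(sim$sweeps)) NULL else
        as.list(sim$sweeps)
    cfgOut$simulation$cnvs <- if (is.null(sim$cnvs)) NULL else
        as.list(sim$cnvs)
    yaml::write_yaml(cfgOut, file.path(outDir, "config_resolved.yaml"))
    invisible(summary)
}

#' A small demonstration pipeline configuration
#'
#' Two 600 kb chromosomes at 1 SNP/kb with one planted fixed-difference
#' sweep window, one case-only copy-number gain and one case-restricted
#' full deletion, sized so the whole run completes in seconds.
#'
#' @param seed master seed.
#' @return A configuration list for [runPipeline()].
#' @export
demoPipelineConfig <- function(seed = 1L) {
    list(seed = as.integer(seed),
         simulation = list(
             sweeps = data.frame(chrom = "chr1", start = 150001,
                                 end = 300000, caseFreq = 1,
                                 controlFreq = 0),
             cnvs = data.frame(chrom = "chr1", start = 400001, end = 403200,
                               caseCN = 3, controlCN = 2),
             deletion = list(chrom = "chr2", start = 200001, end = 208800,
                             samples = c("case1", "case2"),
                             residualFraction = 0)),
         enrichment = list(nTerms = 20L, termSize = 8L))
}
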