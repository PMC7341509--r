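test_that("depth normalization centres samples at diploid copy number", {
    counts <- cbind(a = rep(80L, 30), b = rep(120L, 30))
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, by = 400, length.out = 30), width = 800))
    dwm <- normalizeDepth(DepthWindowMatrix(counts, gr))
    expect_true(all(copyNumber(dwm) == 2))
    ## one window at double coverage -> copy number 4
    counts2 <- counts; counts2[15, "a"] <- 160L
    dwm2 <- normalizeDepth(DepthWindowMatrix(counts2, gr))
    expect_equal(unname(copyNumber(dwm2)[15, "a"]), 4)
    ## an all-zero sample is an error naming the sample
    counts3 <- counts; counts3[, "b"] <- 0L
    expect_error(normalizeDepth(DepthWindowMatrix(counts3, gr)), "b")
})

test_that("normalized copy number recovers a planted gain", {
    cfg <- SimulationConfig(chromosomeLength = 1e5, snpDensity = 0,
        cnvs = data.frame(chrom = "chr1", start = 40001, end = 64000,
                          caseCN = 3, controlCN = 2),
        meanDepth = 100, seed = 37)
    out <- simulateCohort(cfg, tempfile())
    dwm <- normalizeDepth(readDepthWindows(out$depth))
    rr <- SummarizedExperiment::rowRanges(dwm)
    contained <- GenomicRanges::start(rr) >= 40001 &
                 GenomicRanges::end(rr) <= 64000
    expect_gte(sum(contained), 50)
    m <- mean(copyNumber(dwm)[contained, c("case1", "case2")])
    expect_gt(m, 2.8); expect_lt(m, 3.2)
})

test_that("initial calls are maximal runs of extreme windows", {
    cn <- matrix(2, 40, 4, dimnames = list(NULL, paste0("s", 1:4)))
    dwm <- makeDwmFromCn(cn, pad = 0)
    expect_length(initialCalls(dwm), 0)
    cn2 <- cn; cn2[11:20, 2] <- 3
    dwm2 <- makeDwmFromCn(cn2, pad = 0)
    calls <- initialCalls(dwm2)
    expect_length(calls, 1)
    rr <- SummarizedExperiment::rowRanges(dwm2)
    expect_identical(GenomicRanges::start(calls),
                     GenomicRanges::start(rr)[11])
    expect_identical(GenomicRanges::end(calls), GenomicRanges::end(rr)[20])
    ## runs shorter than minWindows are dropped
    cn3 <- cn; cn3[5:6, 1] <- 3
    expect_length(initialCalls(makeDwmFromCn(cn3, pad = 0)), 0)
    ## losses are called too
    cn4 <- cn; cn4[25:30, 3] <- 1
    expect_length(initialCalls(makeDwmFromCn(cn4, pad = 0)), 1)
})

test_that("five planted CNVs are recovered within one window step", {
    cnvs <- data.frame(chrom = "chr1",
                       start = c(20001, 60001, 100001, 140001, 180001),
                       end = c(22800, 63600, 103200, 144000, 184800),
                       caseCN = c(3, 4, 3, 0, 1),
                       controlCN = 2)
    cfg <- SimulationConfig(chromosomeLength = 2.4e5, snpDensity = 0,
                            cnvs = cnvs, meanDepth = 100, seed = 41)
    out <- simulateCohort(cfg, tempfile())
    dwm <- normalizeDepth(readDepthWindows(out$depth))
    calls <- initialCalls(dwm)
    for (i in seq_len(nrow(cnvs))) {
        hit <- which(abs(GenomicRanges::start(calls) - cnvs$start[i]) <= 400)
        expect_length(hit, 1)
        expect_lte(abs(GenomicRanges::end(calls)[hit] - cnvs$end[i]), 400)
    }
})

test_that("merge rule: strict distance cutoff and correlation gate", {
    ## two 10-window calls (4400 bp each) separated by exactly
    ## 0.2 x combined length -> NOT merged (strict <)
    cn <- matrix(2, 60, 8,
                 dimnames = list(NULL, c(paste0("case", 1:2),
                                         paste0("ctrl", 1:6))))
    cn[1:10, 1] <- 3
    ## call A: windows 1..10 -> span 1..4400; a gap of exactly
    ## 0.2 * (4400 + 4400) = 1760 bp is impossible on a 400 bp lattice, so
    ## test the strict boundary with equal-length calls at gap == combined/5
    ## using 11-window calls: len 4800, gap 0.2*(4800+4800) = 1920 = 4.8
    ## steps -- again fractional; use direct interval arithmetic instead.
    dwm <- makeDwmFromCn(cn, pad = 0)
    callA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4000))
    callB <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5601, 9600))
    ## gap = 1600 = 0.2 * (4000 + 4000): not merged
    res <- mergeCalls(c(callA, callB), dwm)
    expect_length(res, 2)
    ## nudge call B one step closer: gap 1200 < 1600; identical per-sample
    ## profiles make the correlation gate pass (r = 1 on case-elevated cn)
    cn2 <- cn; cn2[1:10, 1] <- 3; cn2[16:25, 1] <- 3
    dwm2 <- makeDwmFromCn(cn2, pad = 0)
    callB2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5201, 9200))
    res2 <- mergeCalls(c(callA, callB2), dwm2)
    expect_length(res2, 1)
    expect_identical(GenomicRanges::start(res2), 1L)
    expect_identical(GenomicRanges::end(res2), 9200L)
})

test_that("merging matches the all-pairs brute-force oracle", {
    set.seed(911)
    for (rep in 1:100) {
        nWin <- 80
        nCall <- sample(2:5, 1)
        samples <- c(paste0("case", 1:2), paste0("ctrl", 1:6))
        cn <- matrix(2, nWin, 8, dimnames = list(NULL, samples))
        ## random call windows with case- or shared-elevation patterns
        starts <- sort(sample(seq(1, nWin - 6, by = 4), nCall))
        iv <- NULL
        for (s in starts) {
            len <- sample(3:5, 1)
            rows <- s:min(s + len - 1, nWin)
            who <- sample(list(1, 1:2, c(1, 3, 4)), 1)[[1]]
            cn[rows, who] <- sample(c(0.8, 3, 3.4), 1)
            iv <- rbind(iv, data.frame(chrom = "chr1",
                start = (min(rows) - 1) * 400 + 1,
                end = (max(rows) - 1) * 400 + 800))
        }
        ## drop accidental overlaps from run fusion
        iv <- iv[!duplicated(iv$start), , drop = FALSE]
        iv <- iv[order(iv$start), , drop = FALSE]
        if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) next
        dwm <- makeDwmFromCn(cn, pad = 0)
        calls <- GenomicRanges::GRanges(iv$chrom,
            IRanges::IRanges(iv$start, iv$end))
        res <- mergeCalls(calls, dwm)
        meanCnFun <- function(r) SweepCNV:::.regionMeanCn(
            GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end)),
            dwm)
        oracle <- bruteMergeOracle(iv, meanCnFun, nSamples = 8)
        expect_identical(GenomicRanges::start(res), as.integer(oracle$start))
        expect_identical(GenomicRanges::end(res), as.integer(oracle$end))
        ## order independence: feeding the calls reversed changes nothing
        resRev <- mergeCalls(rev(calls), dwm)
        expect_identical(GenomicRanges::start(resRev),
                         GenomicRanges::start(res))
    }
})

test_that("integer copy number uses half-away-from-zero rounding", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3200))
    cn <- matrix(c(1.98, 3.1, 2.5, 0.02, 1.2, 5.7), 1, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(cn = I(cn))
    rs <- genotypeRegions(new("CNVRegionSet", gr))
    expect_identical(unname(genotypeCodes(rs)[1, ]),
                     c("AA", "AB", "AB", "D", "Ad", "M"))
    expect_identical(unname(unclass(S4Vectors::mcols(rs)$cnInteger)[1, ]),
                     c(2L, 3L, 3L, 0L, 1L, 6L))
})

test_that("Vst matches its definition and the decomposition oracle", {
    ## all samples identical -> Vt = 0 -> Vst = 0
    expect_identical(vstStatistic(c(1, 1), rep(1, 6)), 0)
    ## groups internally identical but different -> Vst = 1
    expect_equal(vstStatistic(c(1, 1), rep(0, 6)), 1)
    ## the worked example: cases {1.0, 0.8}, six controls near 0
    cases <- c(1.0, 0.8)
    ctrls <- c(0.1, -0.1, 0.0, 0.2, -0.2, 0.1)
    expect_equal(vstStatistic(cases, ctrls), vstOracle(cases, ctrls),
                 tolerance = 1e-12)
    expect_error(vstStatistic(numeric(), ctrls), "non-empty")
})

test_that("Vst is bounded, shift-invariant and label-symmetric", {
    set.seed(77)
    for (i in 1:50) {
        ca <- rnorm(2); co <- rnorm(6)
        v <- vstStatistic(ca, co)
        expect_gte(v, 0); expect_lte(v, 1)
        expect_equal(v, vstStatistic(ca + 3.7, co + 3.7), tolerance = 1e-9)
        expect_equal(v, vstStatistic(co, ca), tolerance = 1e-12)
        expect_equal(v, vstOracle(ca, co), tolerance = 1e-12)
    }
    ## the unweighted variant exists and differs for unbalanced groups
    ca <- c(1, 1.2); co <- c(0, 0.4, -0.4, 0.2, -0.2, 0)
    expect_false(isTRUE(all.equal(vstStatistic(ca, co),
                                  vstStatistic(ca, co, weighted = FALSE))))
})

test_that("candidate filtering is strict on both cutoffs", {
    mkRegions <- function(df) {
        gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(df$start, df$start + df$length - 1))
        cn <- matrix(2, nrow(df), 3, dimnames = list(NULL, paste0("s", 1:3)))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(cn = I(cn),
                                                     vst = df$vst)
        new("CNVRegionSet", gr)
    }
    df <- data.frame(chrom = "chr1", start = c(1, 5001, 10001),
                     length = c(2000, 2400, 2400),
                     vst = c(0.9, 0.4357, 0.25))
    out <- filterCandidates(mkRegions(df))
    ## length exactly 2000 removed; vst exactly 0.25 removed;
    ## the 2400 bp / 0.4357 region is retained
    expect_identical(GenomicRanges::start(out), 5001L)
    set.seed(55)
    for (i in 1:100) {
        n <- sample(5:50, 1)
        df <- data.frame(
            chrom = sample(c("chr1", "chr9", "chrX", "scaffold_12"), n,
                           replace = TRUE),
            start = sample.int(1e6, n),
            length = sample(c(1500, 2000, 2001, 3000, 8000), n,
                            replace = TRUE),
            vst = round(stats::runif(n), 3))
        out <- filterCandidates(mkRegions(df))
        oracle <- bruteFilterOracle(df)
        expect_identical(length(out), nrow(oracle))
        expect_setequal(paste(GenomicRanges::seqnames(out),
                              GenomicRanges::start(out)),
                        paste(oracle$chrom, oracle$start))
    }
})

test_that("region-gene annotation reports overlap and signed distance", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 52000))
    cn <- matrix(2, 1, 3, dimnames = list(NULL, paste0("s", 1:3)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(cn = I(cn))
    rs <- new("CNVRegionSet", gr)
    ## a gene starting 43,507 nt after the region end
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(52000 + 43507, width = 5000))
    S4Vectors::mcols(genes)$gene <- "downstreamGene"
    tab <- annotateRegions(rs, genes)
    expect_identical(tab$distance, 43507)
    expect_identical(tab$orientation, "downstream")
    ## overlapping gene -> distance 0
    genes2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(51000, width = 5000))
    S4Vectors::mcols(genes2)$gene <- "overlapping"
    tab2 <- annotateRegions(rs, genes2)
    expect_identical(tab2$distance, 0)
    ## empty annotation -> intergenic
    tab3 <- annotateRegions(rs, GenomicRanges::GRanges())
    expect_identical(tab3$orientation, "intergenic")
})

test_that("nearest-gene assignment matches brute-force search", {
    set.seed(121)
    for (i in 1:30) {
        rs <- sort(sample.int(5e5, 1)); re <- rs + sample(1000:5000, 1)
        nG <- sample(3:10, 1)
        gs <- sample.int(6e5, nG); ge <- gs + sample(500:20000, nG,
                                                     replace = TRUE)
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rs, re))
        cn <- matrix(2, 1, 3, dimnames = list(NULL, paste0("s", 1:3)))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(cn = I(cn))
        genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, ge))
        S4Vectors::mcols(genes)$gene <- sprintf("g%02d", seq_len(nG))
        tab <- annotateRegions(new("CNVRegionSet", gr), genes)
        oracle <- bruteNearestOracle(rs, re, gs, ge,
                                     sprintf("g%02d", seq_len(nG)))
        expect_setequal(tab$gene, oracle$gene)
        expect_identical(unique(tab$distance), oracle$distance)
        expect_identical(unique(tab$orientation), oracle$orientation)
    }
})

test_that("a planted case-only gain survives the whole CNV chain", {
    cfg <- SimulationConfig(chromosomeLength = 2e5, snpDensity = 0,
        cnvs = data.frame(chrom = "chr1", start = 100001, end = 103200,
                          caseCN = 3, controlCN = 2),
        meanDepth = 100, seed = 43)
    out <- simulateCohort(cfg, tempfile())
    dwm <- normalizeDepth(readDepthWindows(out$depth))
    sp <- defaultSplit()
    regions <- regionVst(genotypeRegions(
        mergeCalls(initialCalls(dwm), dwm)), dwm, sp)
    cand <- filterCandidates(regions)
    expect_length(cand, 1)
    expect_gt(vstValues(cand), 0.9)
    geno <- genotypeCodes(cand)[1, ]
    expect_identical(unname(geno[c("case1", "case2")]), c("AB", "AB"))
    expect_true(all(geno[paste0("ctrl", 1:6)] == "AA"))
})
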