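test_that("per-site Fst components behave at the analytic anchor points", {
    ## no differentiation, large samples: numerator ~ 0
    c0 <- fstSiteComponents(0.5, 1000, 0.5, 1000)
    expect_lt(abs(c0$num), 1e-3)
    ## fixed difference: num = den = 1 regardless of sample size
    c1 <- fstSiteComponents(1, 4, 0, 12)
    expect_equal(c1$num, 1); expect_equal(c1$den, 1)
    ## the small-sample correction: p = 0.5 in both groups, n 4 vs 12
    c2 <- fstSiteComponents(0.5, 4, 0.5, 12)
    expect_equal(c2$num, -0.25 / 3 - 0.25 / 11)
    expect_equal(c2$den, 0.5)
    expect_equal(c2$num / c2$den, hudsonFstOracle(0.5, 4, 0.5, 12))
    ## too few alleles: skipped as NA
    expect_true(is.na(fstSiteComponents(0.5, 1, 0.5, 12)$num))
})

test_that("Hudson components agree with an independent formulation", {
    set.seed(101)
    for (i in 1:100) {
        n1 <- 2 * sample(2:10, 1); n2 <- 2 * sample(2:10, 1)
        p1 <- sample(0:n1, 1) / n1; p2 <- sample(0:n2, 1) / n2
        comp <- fstSiteComponents(p1, n1, p2, n2)
        if (comp$den > 0)
            expect_equal(comp$num / comp$den,
                         hudsonFstOracle(p1, n1, p2, n2), tolerance = 1e-12)
        ## symmetry under group swap
        swap <- fstSiteComponents(p2, n2, p1, n1)
        expect_equal(comp$num, swap$num, tolerance = 1e-12)
        expect_equal(comp$den, swap$den, tolerance = 1e-12)
    }
})

test_that("the Weir-Cockerham variant reaches 1 at fixed differences", {
    wc <- fstSiteComponents(1, 4, 0, 12, estimator = "wc")
    expect_equal(wc$num / wc$den, 1)
    wc0 <- fstSiteComponents(0.5, 400, 0.5, 400, estimator = "wc")
    expect_lt(abs(wc0$num / wc0$den), 1e-2)
})

test_that("window Fst tiles from coordinate 1 and combines sites by ratio-of-sums", {
    sp <- defaultSplit()
    gtFixed <- cbind(matrix("1/1", 40, 2), matrix("0/0", 40, 6))
    colnames(gtFixed) <- c("case1", "case2", paste0("ctrl", 1:6))
    v <- makeSites("chr1", seq(1000, by = 10000, length.out = 40), "A", "G",
                   gt = gtFixed)
    w <- windowFst(v, sp, windowSize = 150000, minSnps = 1)
    expect_true(all(GenomicRanges::width(w) == 150000))
    expect_identical(GenomicRanges::start(w), c(1L, 150001L, 300001L))
    expect_true(all(S4Vectors::mcols(w)$fst == 1))
    ## a window with no SNPs is absent from the output
    v2 <- makeSites("chr1", c(1000, 310000), "A", "G", gt = gtFixed[1:2, ])
    w2 <- windowFst(v2, sp, windowSize = 150000, minSnps = 1)
    expect_identical(GenomicRanges::start(w2), c(1L, 300001L))
})

test_that("window Fst validates input ordering and sample names", {
    sp <- defaultSplit()
    v <- makeSites("chr1", c(500, 100), "A", "G")
    expect_error(windowFst(v, sp), "sorted")
    v2 <- makeSites("chr1", c(100, 500), "A", "G")
    badSplit <- PopulationSplit("case1", "nosuch")
    expect_error(windowFst(v2, badSplit), "nosuch")
})

test_that("label swap leaves window Fst unchanged", {
    cfg <- SimulationConfig(chromosomeLength = 3e5, snpDensity = 1e-3,
                            seed = 29)
    out <- simulateAndRead(cfg)
    sp <- defaultSplit()
    flipped <- PopulationSplit(controlSamples(sp), caseSamples(sp))
    w1 <- windowFst(out$variants, sp, windowSize = 50000, minSnps = 5)
    w2 <- windowFst(out$variants, flipped, windowSize = 50000, minSnps = 5)
    expect_equal(S4Vectors::mcols(w1)$fst, S4Vectors::mcols(w2)$fst,
                 tolerance = 1e-12)
})

test_that("window Fst never exceeds 1 and hits 1 only at fixed differences", {
    cfg <- SimulationConfig(chromosomeLength = 3e5, snpDensity = 2e-3,
        sweeps = data.frame(chrom = "chr1", start = 100001, end = 150000,
                            caseFreq = 1, controlFreq = 0), seed = 31)
    out <- simulateAndRead(cfg)
    w <- windowFst(out$variants, defaultSplit(), windowSize = 50000,
                   minSnps = 5)
    expect_true(all(S4Vectors::mcols(w)$fst <= 1 + 1e-12))
    sweepWins <- GenomicRanges::start(w) %in% c(100001, 150001)
    expect_true(any(S4Vectors::mcols(w)$fst[sweepWins] == 1))
})

test_that("ZFst standardization and top-fraction candidate calling", {
    set.seed(7)
    mkWin <- function(fst) {
        g <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(seq(1, by = 150000, length.out = length(fst)),
                             width = 150000))
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(
            nSnps = 50L, fst = fst, retained = TRUE)
        g
    }
    w <- mkWin(stats::runif(200))
    z <- zFstCandidates(w, 0.01)
    expect_identical(sum(S4Vectors::mcols(z)$candidate), 2L)
    expect_lt(abs(mean(S4Vectors::mcols(z)$zfst)), 1e-9)
    expect_lt(abs(stats::sd(S4Vectors::mcols(z)$zfst) - 1), 1e-9)
    ## candidates are exactly the top-k windows
    zv <- S4Vectors::mcols(z)$zfst
    expect_setequal(which(S4Vectors::mcols(z)$candidate),
                    order(zv, decreasing = TRUE)[1:2])
    expect_error(zFstCandidates(mkWin(rep(0.3, 50))), "no variance")
    expect_error(zFstCandidates(mkWin(0.3)), ">= 2")
})

test_that("window annotation uses closed-interval overlap", {
    w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 150000))
    genes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(150001, 149000, 70000), width = c(500, 3000, 100)))
    S4Vectors::mcols(genes)$gene <- c("abutting", "spanning", "inside")
    tab <- annotateWindows(w, genes)
    ## the gene starting at window end + 1 is not reported
    expect_setequal(tab$gene, c("spanning", "inside"))
    ## a gene spanning two windows is reported for both
    w2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 150001), width = 150000))
    tab2 <- annotateWindows(w2, genes[2])
    expect_identical(nrow(tab2), 2L)
    expect_warning(annotateWindows(
        GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)), genes),
        "chromosome")
})

test_that("window-gene assignment matches brute-force interval intersection", {
    set.seed(303)
    for (i in 1:20) {
        nW <- sample(3:8, 1); nG <- sample(5:15, 1)
        ws <- sort(sample(seq(1, 1.2e6, by = 150000), nW))
        w <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(ws, width = 150000))
        gs <- sample.int(1.2e6, nG)
        genes <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(gs, width = sample(100:50000, nG,
                                                replace = TRUE)))
        S4Vectors::mcols(genes)$gene <- sprintf("g%02d", seq_len(nG))
        tab <- annotateWindows(w, genes)
        brute <- do.call(rbind, lapply(seq_len(nW), function(a) {
            hit <- GenomicRanges::start(genes) <= GenomicRanges::end(w)[a] &
                   GenomicRanges::end(genes) >= GenomicRanges::start(w)[a]
            if (!any(hit)) return(NULL)
            data.frame(start = GenomicRanges::start(w)[a],
                       gene = S4Vectors::mcols(genes)$gene[hit])
        }))
        if (is.null(brute)) {
            expect_identical(nrow(tab), 0L)
        } else {
            expect_identical(paste(tab$start, tab$gene),
                             paste(brute$start, brute$gene))
        }
    }
})
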