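## Independent oracles used by the equivalence tests. Each one deliberately
## takes a different route than the package implementation.

## Hudson Fst via the heterozygosity formulation 1 - Hw/Hb, where
## Hw = n1 p1 q1/(n1-1) + n2 p2 q2/(n2-1) and Hb = p1 q2 + p2 q1.
## Algebraically identical to the numerator/denominator route but computed
## through different expressions.
hudsonFstOracle <- function(p1, n1, p2, n2) {
    hw <- n1 * p1 * (1 - p1) / (n1 - 1) + n2 * p2 * (1 - p2) / (n2 - 1)
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    1 - hw / hb
}

## Vst by explicit variance decomposition: between-group variance of the
## group means about the grand mean, divided by total population variance.
vstOracle <- function(caseValues, controlValues) {
    all <- c(caseValues, controlValues)
    N <- length(all)
    grand <- mean(all)
    vt <- sum((all - grand)^2) / N
    if (vt == 0) return(0)
    between <- (length(caseValues) * (mean(caseValues) - grand)^2 +
                length(controlValues) * (mean(controlValues) - grand)^2) / N
    between / vt
}

## Upper-tail hypergeometric P(X >= k) by direct enumeration of the
## probability mass function with choose().
hyperTailOracle <- function(k, K, N, n) {
    ks <- k:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## All-pairs brute-force iterative merge: repeatedly scan every pair of
## regions (not just adjacent ones) in all orders, merge the first
## qualifying pair, and restart until no pair qualifies. meanCnFun maps an
## interval (chrom, start, end) to the per-sample mean copy-number vector.
bruteMergeOracle <- function(iv, meanCnFun, maxGapFraction = 0.2,
                             corAlpha = 0.01, nSamples) {
    qualifies <- function(a, b) {
        if (a$chrom != b$chrom) return(FALSE)
        lo <- if (a$start <= b$start) a else b
        hi <- if (a$start <= b$start) b else a
        gap <- hi$start - lo$end - 1
        lenA <- a$end - a$start + 1; lenB <- b$end - b$start + 1
        if (!(gap < maxGapFraction * (lenA + lenB))) return(FALSE)
        if (nSamples < 3) return(TRUE)
        v1 <- meanCnFun(a); v2 <- meanCnFun(b)
        if (sd(v1) == 0 || sd(v2) == 0) return(TRUE)
        cor.test(v1, v2)$p.value < corAlpha
    }
    repeat {
        merged <- FALSE
        if (nrow(iv) < 2) break
        for (i in seq_len(nrow(iv) - 1)) {
            for (j in seq(i + 1, nrow(iv))) {
                if (qualifies(iv[i, ], iv[j, ])) {
                    iv$start[i] <- min(iv$start[i], iv$start[j])
                    iv$end[i] <- max(iv$end[i], iv$end[j])
                    iv <- iv[-j, , drop = FALSE]
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
        if (!merged) break
    }
    iv[order(iv$chrom, iv$start), , drop = FALSE]
}

## Brute-force candidate filter mirroring the published screening rule.
bruteFilterOracle <- function(df, minLength = 2000, minVst = 0.25,
                              autosomesOnly = TRUE) {
    keep <- df$length > minLength & df$vst > minVst
    if (autosomesOnly) keep <- keep & grepl("^(chr)?[0-9]+$", df$chrom)
    df[keep, , drop = FALSE]
}

## Brute-force nearest/overlap gene search on plain coordinates.
bruteNearestOracle <- function(rs, re, gs, ge, names) {
    ov <- gs <= re & ge >= rs
    if (any(ov))
        return(list(gene = names[ov], distance = 0, orientation = "overlap"))
    dDown <- ifelse(gs > re, gs - re, Inf)
    dUp <- ifelse(ge < rs, rs - ge, Inf)
    d <- pmin(dDown, dUp)
    j <- which.min(d)
    list(gene = names[j], distance = d[j],
         orientation = if (dDown[j] <= dUp[j]) "downstream" else "upstream")
}
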