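#' Read a term-to-gene map
#'
#' Accepts either GMT (`term<TAB>description<TAB>gene1<TAB>gene2...`, one
#' term per line) or a two-column TSV (`term<TAB>gene`, optional header).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return A named list of character gene vectors, with the union of all
#'   genes attached as `attr(, "background")`.
#' @export
readTermMap <- function(path, format = c("auto", "gmt", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (tolower(tools::file_ext(path)) == "gmt") "gmt" else "tsv"
    if (format == "gmt") {
        lines <- readLines(path)
        parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
        tm <- lapply(parts, function(p) unique(p[-(1:2)]))
        names(tm) <- vapply(parts, `[`, "", 1L)
    } else {
        df <- utils::read.delim(path, header = FALSE,
                                colClasses = "character")
        if (tolower(df[1, 1]) %in% c("term", "term_id", "termid"))
            df <- df[-1, , drop = FALSE]
        tm <- lapply(split(df[[2]], df[[1]]), unique)
    }
    tm <- tm[lengths(tm) > 0]
    attr(tm, "background") <- unique(unlist(tm, use.names = FALSE))
    tm
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, tests whether the query gene list overlaps the term's
#' gene set more than expected under uniform sampling from the background:
#' the upper-tail hypergeometric probability of an overlap at least as
#' large as observed. P-values are adjusted across all tested terms by
#' Benjamini-Hochberg. One-sided (over-representation) only.
#'
#' Query genes outside the background are dropped with a message; term
#' gene sets are intersected with the background. Results are independent
#' of term ordering in the input (the table is sorted by p-value, ties by
#' term id).
#'
#' @param query character vector of gene identifiers.
#' @param terms named list of character gene vectors (e.g. from
#'   [readTermMap()] or [simulateTermMap()]).
#' @param background gene universe; default: the map's `background`
#'   attribute, else the union of all term genes.
#' @return A data.frame with one row per term: `term`, `termSize`,
#'   `overlap`, `expected`, `p`, `padj`, `significant` (p < 0.05),
#'   `significantFDR` (padj < 0.05).
#' @export
hypergeometricEnrichment <- function(query, terms, background = NULL) {
    stopifnot(is.list(terms), !is.null(names(terms)))
    if (is.null(background)) background <- attr(terms, "background")
    if (is.null(background))
        background <- unique(unlist(terms, use.names = FALSE))
    background <- unique(as.character(background))
    query <- unique(as.character(query))
    dropped <- setdiff(query, background)
    if (length(dropped))
        message(length(dropped), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
    if (!length(query)) stop("empty query after background intersection")
    N <- length(background); n <- length(query)
    termGenes <- lapply(terms, function(g) intersect(unique(g), background))
    K <- lengths(termGenes)
    k <- vapply(termGenes, function(g) length(intersect(g, query)), 0L)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(term = names(terms), termSize = as.integer(K),
                      overlap = as.integer(k), expected = n * K / N,
                      p = as.numeric(p), row.names = NULL)
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p < 0.05
    out$significantFDR <- out$padj < 0.05
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}
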