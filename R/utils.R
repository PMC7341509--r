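## Deterministic labelled sub-seeding: one master seed, one independent
## stream per output file. Polynomial string hash folded into [0, 2^31).
.subSeed <- function(seed, label) {
    h <- 0
    for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000003
    as.integer((as.numeric(seed) %% 1000003 * 7919 + h * 104729 + 17) %%
               2147483647)
}

## Parse "chr1:100-200" into a GRanges; pass GRanges through untouched.
.asRegion <- function(region) {
    if (is(region, "GRanges")) {
        stopifnot(length(region) == 1L)
        return(region)
    }
    m <- regmatches(region,
        regexec("^([^:]+):([0-9]+)-([0-9]+)$", as.character(region)))[[1]]
    if (length(m) != 4L)
        stop("region must be a GRanges or a 'chrom:start-end' string")
    GRanges(m[2], IRanges(as.numeric(m[3]), as.numeric(m[4])))
}

#' Genomic interval length under both end conventions
#'
#' Interval lengths are reported in two conventions in the wild: 1-based
#' inclusive coordinates give `end - start + 1`, while end-exclusive (BED
#' style) or plain coordinate differences give `end - start`. Both appear in
#' published region descriptions, so the helper makes the convention
#' explicit.
#'
#' @param start,end interval coordinates.
#' @param convention `"inclusive"` (`end - start + 1`) or `"difference"`
#'   (`end - start`).
#' @return numeric length in bp.
#' @examples
#' intervalLength(30003, 38775)                  # 8773
#' intervalLength(247747059, 247755846, "difference")  # 8787
#' @export
intervalLength <- function(start, end,
                           convention = c("inclusive", "difference")) {
    convention <- match.arg(convention)
    stopifnot(all(end >= start))
    if (convention == "inclusive") end - start + 1 else end - start
}

## Read a gene annotation given as GRanges, BED or GFF3 path; returns a
## GRanges with a 'gene' metadata column.
.readGenes <- function(genes) {
    if (!is(genes, "GRanges")) {
        ext <- tolower(tools::file_ext(genes))
        genes <- rtracklayer::import(genes,
            format = if (ext %in% c("gff", "gff3", "gtf")) "gff3" else "bed")
    }
    mc <- mcols(genes)
    nm <- if ("gene" %in% colnames(mc)) mc$gene
          else if ("name" %in% colnames(mc)) mc$name
          else if ("Name" %in% colnames(mc)) mc$Name
          else if ("ID" %in% colnames(mc)) mc$ID
          else if ("gene_id" %in% colnames(mc)) mc$gene_id
          else paste0("feature", seq_along(genes))
    if (!length(genes)) nm <- character(0)
    mcols(genes)$gene <- as.character(nm)
    genes
}

## Warn when query and annotation share no chromosome names.
.checkSeqnames <- function(query, subject, what = "annotation") {
    qs <- unique(as.character(seqnames(query)))
    ss <- unique(as.character(seqnames(subject)))
    un <- setdiff(qs, ss)
    if (length(un) == length(qs) && length(qs))
        warning("no ", what, " chromosome names match the data; unmatched: ",
                paste(un, collapse = ", "))
    invisible(NULL)
}
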