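## Fixed-window tiling, per-window read counting, rpm normalization and the
## CpG-island coverage summary.

#' Tile a genome into fixed windows
#'
#' Non-overlapping tiles of \code{windowSize} bp covering each chromosome
#' from its first base; the terminal partial tile is kept when at least 1 bp
#' remains (it is excluded later from DMR calling, which uses full windows
#' only). With the 500 bp default, printed window starts are 1, 501, 1001,
#' ... matching the published report coordinates.
#'
#' @param chromLengths named integer vector of chromosome lengths, or a
#'   [Biostrings::DNAStringSet] / [SimGenome-class] to take them from.
#' @param windowSize window width in bp.
#' @return A [GenomicRanges::GRanges] of tiles, ordered by chromosome.
#' @examples
#' tileGenomeWindows(c(chr1 = 1250L), windowSize = 500L)
#' @export
tileGenomeWindows <- function(chromLengths, windowSize = 500L) {
    windowSize <- as.integer(windowSize)
    if (is.na(windowSize) || windowSize < 1L) {
        stop("windowSize must be a positive integer")
    }
    if (is(chromLengths, "SimGenome")) chromLengths <- chromLengths@genome
    if (is(chromLengths, "DNAStringSet")) {
        chromLengths <- setNames(
            Biostrings::width(chromLengths),
            names(chromLengths)
        )
    }
    if (is.null(names(chromLengths)) || any(chromLengths < 1)) {
        stop("chromLengths must be a named vector of positive lengths")
    }
    GenomicRanges::tileGenome(chromLengths,
        tilewidth = windowSize,
        cut.last.tile.in.chrom = TRUE
    )
}

.dedupReads <- function(reads) {
    key <- paste(
        as.character(seqnames(reads)), start(reads), end(reads),
        as.character(strand(reads))
    )
    reads[!duplicated(key)]
}

## leftmost coordinate of each read, strand ignored (assignment rule)
.readAnchors <- function(reads) {
    GRanges(seqnames(reads), IRanges(start(reads), width = 1L))
}

#' Count capture reads in genome windows for two libraries
#'
#' Each read is assigned to exactly one window: the tile containing its
#' leftmost coordinate. Reads on chromosomes absent from the tiling are
#' tallied in a per-library \code{unplaced} bucket rather than dropped, so
#' window counts plus unplaced always conserve the input totals. rpm is
#' count x 1e6 / library size, where the library size is the number of reads
#' supplied for that condition (after deduplication if requested).
#'
#' @param windows tiles from [tileGenomeWindows()].
#' @param readsA,readsB [GenomicRanges::GRanges] of aligned reads for
#'   conditions A and B.
#' @param dedup remove exact-coordinate duplicate reads first (default
#'   FALSE; the rpm library size is taken after removal).
#' @return A [WindowCounts-class] object.
#' @export
countWindowReads <- function(windows, readsA, readsB, dedup = FALSE) {
    stopifnot(is(windows, "GRanges"))
    if (isTRUE(dedup)) {
        readsA <- .dedupReads(readsA)
        readsB <- .dedupReads(readsB)
    }
    one <- function(reads) {
        if (length(reads) == 0L) {
            return(list(counts = integer(length(windows)), unplaced = 0L))
        }
        anchors <- .readAnchors(reads)
        hit <- findOverlaps(anchors, windows, select = "first")
        list(
            counts = tabulate(hit, nbins = length(windows)),
            unplaced = sum(is.na(hit))
        )
    }
    a <- one(readsA)
    b <- one(readsB)
    counts <- cbind(A = a$counts, B = b$counts)
    libSize <- c(A = max(length(readsA), 1L), B = max(length(readsB), 1L))
    rpm <- sweep(counts, 2L, libSize, function(x, n) x * 1e6 / n)
    windowSize <- if (length(windows)) {
        max(BiocGenerics::width(windows))
    } else {
        NA_integer_
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts, rpm = rpm),
        rowRanges = windows,
        colData = S4Vectors::DataFrame(
            librarySize = unname(libSize),
            unplaced = c(a$unplaced, b$unplaced),
            row.names = c("A", "B")
        ),
        metadata = list(windowSize = windowSize)
    )
    new("WindowCounts", se)
}

#' Reads-per-million normalization
#'
#' @param counts integer read counts.
#' @param librarySize total mapped reads in the library.
#' @return Numeric rpm values, \code{counts * 1e6 / librarySize}.
#' @examples
#' rpmNormalize(20, 1e6)
#' @export
rpmNormalize <- function(counts, librarySize) {
    if (any(librarySize <= 0)) stop("librarySize must be positive")
    if (any(counts < 0)) stop("counts must be non-negative")
    counts * 1e6 / librarySize
}

#' Library-level CpG-island coverage summary
#'
#' Computes, for one library, the published CGI coverage descriptors: reads
#' inside CGIs (by assigned leftmost coordinate), their percentage of total
#' reads, the number and percentage of CGIs covered by at least one read,
#' and the mean depth per covered CGI (reads in CGIs / CGIs covered).
#'
#' @param reads [GenomicRanges::GRanges] of reads.
#' @param cgi the CGI track.
#' @param totalReads denominator for the percentage (defaults to the number
#'   of reads supplied; pass the raw sequencing total to reproduce summaries
#'   quoted against raw reads).
#' @return A one-row data.frame; see [libraryStats()].
#' @export
cgiStats <- function(reads, cgi, totalReads = length(reads)) {
    if (length(cgi) == 0L) stop("CGI track is empty")
    anchors <- .readAnchors(reads)
    readsInCgi <- sum(overlapsAny(anchors, cgi))
    cgisCovered <- sum(countOverlaps(cgi, anchors) > 0L)
    libraryStats(readsInCgi, totalReads, cgisCovered, length(cgi))
}

#' Assemble CGI coverage statistics from their defining counts
#'
#' The arithmetic layer beneath [cgiStats()], usable directly on published
#' counts: percentage of reads in CGIs = 100 x reads_in_cgi / total_reads;
#' mean per-covered-CGI depth = reads_in_cgi / cgis_covered. Zero
#' denominators give 0 with \code{degenerate = TRUE}.
#'
#' @param readsInCgi,totalReads,cgisCovered,totalCgis the defining counts
#'   (\code{totalCgis} may be NA when unknown).
#' @return A one-row data.frame with columns total_reads, reads_in_cgi,
#'   cgi_fraction_pct, cgis_covered, cgis_covered_pct, per_cgi_depth,
#'   degenerate.
#' @examples
#' libraryStats(314334, 21763035, 19582, 28691)
#' @export
libraryStats <- function(readsInCgi, totalReads, cgisCovered,
                         totalCgis = NA_integer_) {
    if (readsInCgi > totalReads) {
        stop("reads_in_cgi cannot exceed total_reads")
    }
    if (!is.na(totalCgis) && cgisCovered > totalCgis) {
        stop("cgis_covered cannot exceed the number of CGIs")
    }
    degenerate <- totalReads == 0 || cgisCovered == 0
    data.frame(
        total_reads = totalReads,
        reads_in_cgi = readsInCgi,
        cgi_fraction_pct = if (totalReads > 0) {
            100 * readsInCgi / totalReads
        } else {
            0
        },
        cgis_covered = cgisCovered,
        cgis_covered_pct = if (!is.na(totalCgis) && totalCgis > 0) {
            100 * cgisCovered / totalCgis
        } else {
            NA_real_
        },
        per_cgi_depth = if (cgisCovered > 0) readsInCgi / cgisCovered else 0,
        degenerate = degenerate
    )
}
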