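#' @useDynLib MethCapDMR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   letterFrequency vcountPattern matchPattern subseq
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowRanges rowData<-
#' @importFrom stats dhyper p.adjust rbeta rmultinom runif setNames
#' @importFrom utils read.table write.table packageVersion
#' @importFrom tools md5sum
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration for the MBD-capture generator
#'
#' Holds every parameter of the synthetic study: the toy genome geometry
#' (chromosomes, genes, CpG islands, repeats), the dinucleotide composition
#' targets, the two-condition regional methylation model with planted
#' differentially methylated regions (DMRs), and the capture-read sampler.
#'
#' All randomness in the simulator derives from \code{seed}; operations use a
#' fixed stream order (\code{seed} for the genome, \code{seed + 1} for the
#' methylomes, \code{seed + 2} and \code{seed + 3} for the two read
#' libraries), so identical configurations give byte-identical outputs.
#'
#' @slot seed integer master seed.
#' @slot nChroms,chromLength integer; number of chromosomes and their common
#'   length in bp.
#' @slot nGenes,nCgis,nRepeats integer feature counts. The first
#'   \code{min(nCgis, nGenes)} CpG islands are centred on gene TSSs
#'   (promoter CGIs); any excess islands are placed in intergenic space.
#' @slot cgiTargetOE,backgroundOE numeric target CpG observed/expected ratio
#'   inside CGIs and in background sequence.
#' @slot gcBackground,gcCgi numeric GC content of background and CGI sequence.
#' @slot nDmrs integer number of planted DMR regions.
#' @slot methHigh,methLow,methBackground numeric in [0,1]; methylation level
#'   of the hyper- and hypo-methylated side of a planted DMR, and the mean of
#'   the Beta-distributed background regional methylation shared by both
#'   conditions.
#' @slot dmrPlacement character; where DMR regions are planted. One of
#'   \code{"background"} (CpG-poor regions away from genes/CGIs/repeats, the
#'   default), \code{"cgi"}, \code{"repeat"} or \code{"any"}.
#' @slot regionLength integer bp; length of the uniform-methylation regions
#'   the genome is partitioned into (CGIs always form their own regions).
#' @slot readsPerLibrary integer reads emitted per condition.
#' @slot fragmentLength,readLength integer bp; captured fragment size and the
#'   single-end read length cut from it.
#' @slot cgiLength,repeatLength,geneLength integer bp feature sizes.
#' @slot samplingFloor numeric; fragment sampling weight floor expressed as a
#'   fraction of the maximum raw weight, so fully unmethylated sequence still
#'   receives a trickle of reads (capture carryover).
#' @seealso [SimConfig()] for the user constructor with defaults.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        seed = "integer",
        nChroms = "integer",
        chromLength = "integer",
        nGenes = "integer",
        nCgis = "integer",
        nRepeats = "integer",
        cgiTargetOE = "numeric",
        backgroundOE = "numeric",
        gcBackground = "numeric",
        gcCgi = "numeric",
        nDmrs = "integer",
        methHigh = "numeric",
        methLow = "numeric",
        methBackground = "numeric",
        dmrPlacement = "character",
        regionLength = "integer",
        readsPerLibrary = "integer",
        fragmentLength = "integer",
        readLength = "integer",
        cgiLength = "integer",
        repeatLength = "integer",
        geneLength = "integer",
        samplingFloor = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    counts <- c(
        nChroms = object@nChroms, chromLength = object@chromLength,
        nGenes = object@nGenes, nCgis = object@nCgis,
        nRepeats = object@nRepeats, nDmrs = object@nDmrs,
        readsPerLibrary = object@readsPerLibrary
    )
    if (any(is.na(counts)) || any(counts < 0)) {
        msg <- c(msg, "all counts must be non-negative")
    }
    if (object@nChroms < 1 || object@chromLength < 1) {
        msg <- c(msg, "need at least one chromosome of positive length")
    }
    fr <- c(object@methHigh, object@methLow, object@methBackground)
    if (any(fr < 0) || any(fr > 1)) {
        msg <- c(msg, "methylation levels must lie in [0, 1]")
    }
    if (object@fragmentLength < object@readLength) {
        msg <- c(msg, "fragmentLength must be >= readLength")
    }
    if (object@readLength < 1) msg <- c(msg, "readLength must be positive")
    if (object@cgiTargetOE < 0 || object@backgroundOE < 0) {
        msg <- c(msg, "CpG o/e targets must be non-negative")
    }
    if (object@gcBackground <= 0 || object@gcBackground >= 1 ||
        object@gcCgi <= 0 || object@gcCgi >= 1) {
        msg <- c(msg, "GC contents must lie in (0, 1)")
    }
    if (object@samplingFloor < 0) {
        msg <- c(msg, "samplingFloor must be non-negative")
    }
    if (object@regionLength < 500 || object@regionLength %% 500L != 0L) {
        msg <- c(msg, "regionLength must be a positive multiple of 500 bp")
    }
    if (object@cgiLength < 500 || object@cgiLength %% 500L != 0L) {
        msg <- c(msg, "cgiLength must be a positive multiple of 500 bp")
    }
    if (!object@dmrPlacement %in% c("background", "cgi", "repeat", "any")) {
        msg <- c(msg, "dmrPlacement must be one of background/cgi/repeat/any")
    }
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe the study conditions the package's calibration suites
#' run under: a 2 x 300 kb toy genome (1200 full 500 bp windows), 20 genes
#' with 1 kb promoter CpG islands (target CpG o/e 0.9 vs 0.3 background),
#' 10 repeats, 20 planted 5 kb DMR blocks of methylation 0.9 vs 0.05 over a
#' Beta(4,6) background (mean 0.4), and 22,000 single-end 36 bp reads per
#' library cut from 400 bp captured fragments (about 30 expected reads in
#' each planted DMR window).
#'
#' @param seed integer master seed.
#' @param nChroms,chromLength genome geometry (bp).
#' @param nGenes,nCgis,nRepeats feature counts.
#' @param cgiTargetOE,backgroundOE CpG observed/expected targets.
#' @param gcBackground,gcCgi GC content of the two sequence classes.
#' @param nDmrs number of planted DMR regions.
#' @param methHigh,methLow,methBackground methylation levels in [0,1].
#' @param dmrPlacement one of "background", "cgi", "repeat", "any".
#' @param regionLength bp length of uniform-methylation regions.
#' @param readsPerLibrary reads per condition.
#' @param fragmentLength,readLength captured fragment and read length (bp).
#' @param cgiLength,repeatLength,geneLength feature sizes (bp).
#' @param samplingFloor weight floor as a fraction of the max fragment weight.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 42L, nDmrs = 10L)
#' cfg
#' @export
SimConfig <- function(seed = 1L,
                      nChroms = 2L,
                      chromLength = 300000L,
                      nGenes = 20L,
                      nCgis = 20L,
                      nRepeats = 10L,
                      cgiTargetOE = 0.9,
                      backgroundOE = 0.3,
                      gcBackground = 0.40,
                      gcCgi = 0.60,
                      nDmrs = 20L,
                      methHigh = 0.9,
                      methLow = 0.05,
                      methBackground = 0.4,
                      dmrPlacement = "background",
                      regionLength = 5000L,
                      readsPerLibrary = 22000L,
                      fragmentLength = 400L,
                      readLength = 36L,
                      cgiLength = 1000L,
                      repeatLength = 1000L,
                      geneLength = 4000L,
                      samplingFloor = 1e-3) {
    new("SimConfig",
        seed = as.integer(seed), nChroms = as.integer(nChroms),
        chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
        nCgis = as.integer(nCgis), nRepeats = as.integer(nRepeats),
        cgiTargetOE = cgiTargetOE, backgroundOE = backgroundOE,
        gcBackground = gcBackground, gcCgi = gcCgi,
        nDmrs = as.integer(nDmrs), methHigh = methHigh, methLow = methLow,
        methBackground = methBackground,
        dmrPlacement = match.arg(dmrPlacement,
            c("background", "cgi", "repeat", "any")),
        regionLength = as.integer(regionLength),
        readsPerLibrary = as.integer(readsPerLibrary),
        fragmentLength = as.integer(fragmentLength),
        readLength = as.integer(readLength),
        cgiLength = as.integer(cgiLength),
        repeatLength = as.integer(repeatLength),
        geneLength = as.integer(geneLength),
        samplingFloor = samplingFloor
    )
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf(
        "  genome: %d chrom(s) x %d bp; %d genes, %d CGIs, %d repeats\n",
        object@nChroms, object@chromLength, object@nGenes, object@nCgis,
        object@nRepeats
    ))
    cat(sprintf(
        "  CpG o/e targets: CGI %.2f / background %.2f (GC %.2f / %.2f)\n",
        object@cgiTargetOE, object@backgroundOE, object@gcCgi,
        object@gcBackground
    ))
    cat(sprintf(
        "  methylomes: %d DMRs (%s), meth %.2f vs %.2f over background %.2f\n",
        object@nDmrs, object@dmrPlacement, object@methHigh, object@methLow,
        object@methBackground
    ))
    cat(sprintf(
        "  reads: %d x %d bp per library from %d bp fragments (seed %d)\n",
        object@readsPerLibrary, object@readLength, object@fragmentLength,
        object@seed
    ))
    invisible(NULL)
})

#' DMR filter thresholds
#'
#' The three-part filter applied to every full-width window: maximum rpm
#' above \code{rpmMin}, rpm ratio above \code{ratioMin}, and exact-test
#' p-value below \code{pMax}. All inequalities are strict. Defaults are
#' 500 bp windows, rpm > 20, ratio > 20 and p < 0.001.
#'
#' @slot windowSize integer window width in bp.
#' @slot rpmMin,ratioMin,pMax numeric thresholds.
#' @exportClass DmrFilter
setClass("DmrFilter",
    representation(
        windowSize = "integer",
        rpmMin = "numeric",
        ratioMin = "numeric",
        pMax = "numeric"
    )
)

setValidity("DmrFilter", function(object) {
    thr <- c(object@windowSize, object@rpmMin, object@ratioMin, object@pMax)
    if (any(is.na(thr)) || any(thr <= 0)) {
        return("all thresholds must be positive")
    }
    if (object@pMax > 1) return("pMax must be a probability")
    TRUE
})

#' @param windowSize,rpmMin,ratioMin,pMax filter thresholds; see
#'   [DmrFilter-class].
#' @return A validated \code{DmrFilter} object.
#' @rdname DmrFilter-class
#' @examples
#' DmrFilter()
#' @export
DmrFilter <- function(windowSize = 500L, rpmMin = 20, ratioMin = 20,
                      pMax = 0.001) {
    new("DmrFilter",
        windowSize = as.integer(windowSize), rpmMin = rpmMin,
        ratioMin = ratioMin, pMax = pMax
    )
}

setMethod("show", "DmrFilter", function(object) {
    cat(sprintf(
        "DmrFilter: %d bp windows, rpm > %g, ratio > %g, p < %g\n",
        object@windowSize, object@rpmMin, object@ratioMin, object@pMax
    ))
    invisible(NULL)
})

#' Simulated toy genome with annotation tracks
#'
#' Container returned by [simulateGenome()]: the chromosome sequences plus
#' the gene models, exon structure, CpG-island and repeat tracks laid down
#' on them. All coordinates are 1-based inclusive (GRanges convention).
#'
#' @slot genome a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes a [GenomicRanges::GRanges] of gene spans with metadata columns
#'   \code{gene_id} and \code{tss} (strand-aware transcription start site).
#' @slot exons a [GenomicRanges::GRangesList] of exon blocks, one element per
#'   gene, in genomic order.
#' @slot cgi,repeats [GenomicRanges::GRanges] tracks.
#' @exportClass SimGenome
setClass("SimGenome",
    representation(
        genome = "DNAStringSet",
        genes = "GRanges",
        exons = "GRangesList",
        cgi = "GRanges",
        repeats = "GRanges"
    )
)

setMethod("show", "SimGenome", function(object) {
    cat(sprintf(
        "SimGenome: %d chromosome(s), %s bp total; %d genes, %d CGIs, %d repeats\n",
        length(object@genome),
        format(sum(Biostrings::width(object@genome)), big.mark = ","),
        length(object@genes), length(object@cgi), length(object@repeats)
    ))
    invisible(NULL)
})

#' Per-window read counts for two capture libraries
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' fixed genome tiles and whose two columns are the conditions ("A", "B").
#' Assays \code{counts} (integer reads assigned by leftmost read coordinate)
#' and \code{rpm} (reads per million, count x 1e6 / library size). Column
#' data records the library size used for normalization and the number of
#' reads that fell on chromosomes absent from the tiling (\code{unplaced}).
#'
#' @seealso [countWindowReads()], [testWindows()], [callDmrs()]
#' @exportClass WindowCounts
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
    msg <- character()
    if (!all(c("counts", "rpm") %in%
        SummarizedExperiment::assayNames(object))) {
        msg <- c(msg, "assays 'counts' and 'rpm' are required")
    }
    if (ncol(object) != 2L || !identical(colnames(object), c("A", "B"))) {
        msg <- c(msg, "exactly two columns named 'A' and 'B' are required")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("librarySize", "unplaced") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'librarySize' and 'unplaced'")
    } else if (any(cd$librarySize <= 0)) {
        msg <- c(msg, "library sizes must be positive")
    }
    if ("counts" %in% SummarizedExperiment::assayNames(object) &&
        any(SummarizedExperiment::assay(object, "counts") < 0)) {
        msg <- c(msg, "counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn WindowCounts library sizes used for rpm normalization.
#' @param x a \code{WindowCounts} object.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname WindowCounts-class
#' @export
setMethod("librarySizes", "WindowCounts", function(x) {
    setNames(
        SummarizedExperiment::colData(x)$librarySize,
        colnames(x)
    )
})

#' @describeIn WindowCounts reads per chromosome absent from the tiling.
#' @export
setGeneric("unplacedReads", function(x) standardGeneric("unplacedReads"))

#' @rdname WindowCounts-class
#' @export
setMethod("unplacedReads", "WindowCounts", function(x) {
    setNames(SummarizedExperiment::colData(x)$unplaced, colnames(x))
})

#' @describeIn WindowCounts rpm matrix (reads per million per window).
#' @export
setGeneric("rpmValues", function(x) standardGeneric("rpmValues"))

#' @rdname WindowCounts-class
#' @export
setMethod("rpmValues", "WindowCounts", function(x) {
    SummarizedExperiment::assay(x, "rpm")
})

setMethod("show", "WindowCounts", function(object) {
    callNextMethod()
    cat(sprintf(
        "window size: %s bp; library sizes: A=%d, B=%d; unplaced: A=%d, B=%d\n",
        as.character(S4Vectors::metadata(object)$windowSize %||% "?"),
        librarySizes(object)[["A"]], librarySizes(object)[["B"]],
        unplacedReads(object)[["A"]], unplacedReads(object)[["B"]]
    ))
    invisible(NULL)
})
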