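## Per-window differential test and DMR calling under the three-part filter
## (rpm > rpmMin, rpm ratio > ratioMin, p < pMax; all strict).

## two-sided Fisher's exact p for one 2x2 table
## [[a, libA - a], [b, libB - b]]: sum of hypergeometric point masses not
## exceeding the observed one (same (1 + 1e-7) relative guard as the
## classical implementation, so ties on the opposite tail are included).
.fisher2x2 <- function(a, b, libA, libB) {
    k <- a + b
    if (k == 0) {
        return(1)
    }
    lo <- max(0, k - libB)
    hi <- min(k, libA)
    x <- lo:hi
    d <- dhyper(x, libA, libB, k)
    pObs <- dhyper(a, libA, libB, k)
    min(1, sum(d[d <= pObs * (1 + 1e-7)]))
}

#' Two-sided exact test for differential window counts
#'
#' Fisher's exact test on the 2x2 table of a window's read count against the
#' remainder of each library: \code{[[countA, libA - countA], [countB,
#' libB - countB]]}. This is the defined differential test of the pipeline:
#' exact, assumption-light and symmetric in the two conditions. Vectorized
#' over windows.
#'
#' @param countA,countB per-window read counts.
#' @param libA,libB library sizes (total mapped reads).
#' @return Two-sided p-value(s) in [0, 1].
#' @examples
#' fisherWindowTest(5, 5, 1e6, 1e6) # balanced table: p = 1
#' fisherWindowTest(0, 30, 1e6, 1e6)
#' @export
fisherWindowTest <- function(countA, countB, libA, libB) {
    n <- max(length(countA), length(countB))
    countA <- rep_len(as.numeric(countA), n)
    countB <- rep_len(as.numeric(countB), n)
    libA <- rep_len(as.numeric(libA), n)
    libB <- rep_len(as.numeric(libB), n)
    if (any(is.na(countA)) || any(is.na(countB))) stop("counts must not be NA")
    if (any(countA < 0) || any(countB < 0)) stop("counts must be non-negative")
    if (any(libA <= 0) || any(libB <= 0)) {
        stop("library sizes must be positive")
    }
    if (any(countA > libA) || any(countB > libB)) {
        stop("counts cannot exceed their library size")
    }
    vapply(
        seq_len(n),
        function(i) .fisher2x2(countA[i], countB[i], libA[i], libB[i]),
        numeric(1)
    )
}

#' Score every window for differential capture
#'
#' Adds per-window statistics to the rowData of a [WindowCounts-class]
#' object: the rpm pair, the rpm ratio (max/min; \code{Inf} when the minor
#' library has zero reads, NA when both are zero), the two-sided exact-test
#' p-value, an informational BH-adjusted p (no correction enters the
#' filter), the direction of the larger rpm, and whether the window has full
#' width (terminal partial tiles are never called).
#'
#' @param wc a [WindowCounts-class] object.
#' @return The same object with rowData columns \code{ratio},
#'   \code{p_value}, \code{fdr}, \code{direction}, \code{full_width}.
#' @export
testWindows <- function(wc) {
    stopifnot(is(wc, "WindowCounts"))
    counts <- assay(wc, "counts")
    rpm <- assay(wc, "rpm")
    libs <- librarySizes(wc)
    hiRpm <- pmax(rpm[, "A"], rpm[, "B"])
    loRpm <- pmin(rpm[, "A"], rpm[, "B"])
    ratio <- ifelse(hiRpm == 0, NA_real_, hiRpm / loRpm)
    p <- fisherWindowTest(counts[, "A"], counts[, "B"], libs["A"], libs["B"])
    direction <- ifelse(rpm[, "A"] > rpm[, "B"], "A_hyper",
        ifelse(rpm[, "B"] > rpm[, "A"], "B_hyper", "none")
    )
    windowSize <- S4Vectors::metadata(wc)$windowSize
    full <- BiocGenerics::width(rowRanges(wc)) == windowSize
    fdr <- rep(NA_real_, length(p))
    fdr[full] <- p.adjust(p[full], method = "BH")
    rowData(wc)$ratio <- ratio
    rowData(wc)$p_value <- p
    rowData(wc)$fdr <- fdr
    rowData(wc)$direction <- direction
    rowData(wc)$full_width <- full
    wc
}

#' Call differentially methylated regions
#'
#' Reports every full-width window passing the three-part filter with strict
#' inequalities: max(rpm) > \code{rpmMin}, rpm ratio > \code{ratioMin}
#' (infinite ratios pass), and exact-test p < \code{pMax}. Adjacent passing
#' windows are reported separately (no merging), mirroring the published
#' consecutive 500 bp report rows.
#'
#' @param wc a [WindowCounts-class] object (scored with [testWindows()] if
#'   not already).
#' @param filter a [DmrFilter-class] (study defaults: 500 bp, rpm > 20,
#'   ratio > 20, p < 0.001).
#' @return A [GenomicRanges::GRanges] of called windows with metadata
#'   columns \code{rpm_A}, \code{rpm_B}, \code{ratio}, \code{p_value},
#'   \code{fdr} and \code{direction} (\code{A_hyper}/\code{B_hyper});
#'   the filter and the number of windows tested are kept in
#'   \code{metadata()}.
#' @export
callDmrs <- function(wc, filter = DmrFilter()) {
    stopifnot(is(wc, "WindowCounts"), is(filter, "DmrFilter"))
    validObject(filter)
    if (!"p_value" %in% colnames(rowData(wc))) wc <- testWindows(wc)
    rd <- rowData(wc)
    rpm <- assay(wc, "rpm")
    hiRpm <- pmax(rpm[, "A"], rpm[, "B"])
    pass <- rd$full_width &
        BiocGenerics::width(rowRanges(wc)) == filter@windowSize &
        hiRpm > filter@rpmMin &
        !is.na(rd$ratio) & rd$ratio > filter@ratioMin &
        rd$p_value < filter@pMax
    out <- granges(rowRanges(wc)[pass])
    mcols(out) <- S4Vectors::DataFrame(
        rpm_A = rpm[pass, "A"], rpm_B = rpm[pass, "B"],
        ratio = rd$ratio[pass], p_value = rd$p_value[pass],
        fdr = rd$fdr[pass],
        direction = factor(rd$direction[pass],
            levels = c("A_hyper", "B_hyper")
        )
    )
    S4Vectors::metadata(out) <- list(
        filter = filter,
        nTested = sum(rd$full_width)
    )
    out
}

#' Compare called DMRs with the simulator ground truth
#'
#' Sensitivity is the fraction of planted DMR regions overlapped by at least
#' one called window; precision is the fraction of called windows
#' overlapping a planted region. Vacuous cases (no planted regions, no
#' calls) report 1.0 with an explicit flag.
#'
#' @param dmrs called windows from [callDmrs()].
#' @param truth truth data.frame from [simulateMethylomes()] (or read back
#'   with [readTruthTable()]).
#' @return A list: \code{sensitivity}, \code{precision}, \code{nPlanted},
#'   \code{nCalled}, \code{vacuousSensitivity}, \code{vacuousPrecision}.
#' @export
recoverTruth <- function(dmrs, truth) {
    planted <- truth[truth$is_dmr, , drop = FALSE]
    plantedGr <- GRanges(planted$chrom, IRanges(planted$start, planted$end))
    vacS <- nrow(planted) == 0L
    vacP <- length(dmrs) == 0L
    sensitivity <- if (vacS) 1 else mean(overlapsAny(plantedGr, dmrs))
    precision <- if (vacP) 1 else mean(overlapsAny(dmrs, plantedGr))
    list(
        sensitivity = sensitivity, precision = precision,
        nPlanted = nrow(planted), nCalled = length(dmrs),
        vacuousSensitivity = vacS, vacuousPrecision = vacP
    )
}
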