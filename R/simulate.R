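## Synthetic MBD-capture data: toy genome, two methylomes with planted DMRs,
## and capture reads whose sampling weight follows methylated-CpG content.

.baseProbs <- function(gc) {
    c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

## one sequence from the two-state dinucleotide chain (compiled)
.simSeq <- function(n, gc, oe) {
    q <- .baseProbs(gc)
    pG <- min(oe * q[["G"]], 0.95)
    .markov_dinuc(as.integer(n), unname(q), pG)
}

#' Simulate a toy genome with genes, CpG islands and repeats
#'
#' Lays out non-overlapping feature "slots" along each chromosome
#' (interleaved across chromosomes), placing genes with strand-aware TSSs,
#' 1 kb window-grid-aligned CpG islands centred on gene TSSs (promoter
#' CGIs; islands in excess of the gene count become intergenic orphans),
#' and repeats in their own slots. Background sequence is drawn from a
#' two-state dinucleotide chain tuned to \code{backgroundOE}; CGI intervals
#' are overwritten with sequence tuned to \code{cgiTargetOE}, so the CpG
#' observed/expected ratio separates the two classes while GC content stays
#' controlled.
#'
#' Uses the RNG stream seeded with \code{config@seed}; identical
#' configurations give byte-identical genomes.
#'
#' @param config a [SimConfig-class] object.
#' @return A [SimGenome-class] object.
#' @examples
#' sim <- simulateGenome(SimConfig(seed = 1L, chromLength = 50000L,
#'     nGenes = 2L, nCgis = 2L, nRepeats = 1L))
#' sim
#' @export
simulateGenome <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    L <- config@chromLength
    chroms <- paste0("chr", seq_len(config@nChroms))
    si <- GenomeInfoDb::Seqinfo(chroms, rep(L, config@nChroms))

    nPromCgi <- min(config@nCgis, config@nGenes)
    nOrphan <- config@nCgis - nPromCgi
    nFeat <- config@nGenes + config@nRepeats + nOrphan

    geneDf <- NULL
    repGr <- GRanges(seqinfo = si)
    cgiGr <- GRanges(seqinfo = si)

    if (nFeat > 0L) {
        slotsPerChrom <- ceiling(nFeat / config@nChroms)
        slotW <- ((L %/% slotsPerChrom) %/% 500L) * 500L
        minW <- 2L * max(
            5000L + config@cgiLength %/% 2L + 500L,
            config@geneLength + 500L,
            config@repeatLength + 500L
        )
        if (slotW < minW) {
            stop(
                "genome capacity exceeded: ", nFeat, " features on ",
                config@nChroms, " chromosome(s) of ", L, " bp leave ",
                slotW, " bp per feature slot but at least ", minW,
                " bp are needed (gene span + promoter + CGI footprint); ",
                "reduce feature counts or enlarge the genome",
                call. = FALSE
            )
        }
        ## slots interleaved: chr1 slot1, chr2 slot1, chr1 slot2, ...
        slotChrom <- rep(chroms, slotsPerChrom)[seq_len(nFeat)]
        slotIdx <- rep(seq_len(slotsPerChrom), each = config@nChroms)[
            seq_len(nFeat)
        ]
        ## 0-based anchors on the 500 bp window grid
        anchor0 <- (slotIdx - 1L) * slotW + (slotW %/% 1000L) * 500L

        take <- function(n, from) seq_len(n) + from
        gi <- take(config@nGenes, 0L)
        ri <- take(config@nRepeats, config@nGenes)
        oi <- take(nOrphan, config@nGenes + config@nRepeats)

        if (config@nGenes > 0L) {
            strand <- rep(c("+", "-"), length.out = config@nGenes)
            a0 <- anchor0[gi]
            tss <- ifelse(strand == "+", a0 + 1L, a0)
            gstart <- ifelse(strand == "+", tss, tss - config@geneLength + 1L)
            gend <- ifelse(strand == "+", tss + config@geneLength - 1L, tss)
            geneDf <- data.frame(
                gene_id = sprintf("gene%03d", seq_len(config@nGenes)),
                chrom = slotChrom[gi], strand = strand,
                tss = as.integer(tss), start = as.integer(gstart),
                end = as.integer(gend), stringsAsFactors = FALSE
            )
        }
        if (config@nRepeats > 0L) {
            repGr <- GRanges(slotChrom[ri],
                IRanges(anchor0[ri] + 1L, anchor0[ri] + config@repeatLength),
                seqinfo = si
            )
            names(repGr) <- sprintf("repeat%03d", seq_len(config@nRepeats))
        }
        half <- config@cgiLength %/% 2L
        cgiAnchor <- c(
            if (nPromCgi > 0L) anchor0[gi][seq_len(nPromCgi)],
            if (nOrphan > 0L) anchor0[oi]
        )
        cgiChrom <- c(
            if (nPromCgi > 0L) slotChrom[gi][seq_len(nPromCgi)],
            if (nOrphan > 0L) slotChrom[oi]
        )
        if (config@nCgis > 0L) {
            cgiGr <- GRanges(cgiChrom,
                IRanges(cgiAnchor - half + 1L, cgiAnchor + half),
                seqinfo = si
            )
            names(cgiGr) <- sprintf("cgi%03d", seq_len(config@nCgis))
            cgiGr <- sort(cgiGr)
        }
    }

    ## sequences: background chain per chromosome, then CGI overwrites,
    ## in a fixed RNG stream order
    set.seed(config@seed)
    seqs <- vapply(
        chroms,
        function(chr) .simSeq(L, config@gcBackground, config@backgroundOE),
        character(1)
    )
    if (length(cgiGr)) {
        for (i in seq_along(cgiGr)) {
            chr <- as.character(seqnames(cgiGr)[i])
            cseq <- .simSeq(
                BiocGenerics::width(cgiGr)[i],
                config@gcCgi, config@cgiTargetOE
            )
            substr(seqs[[chr]], start(cgiGr)[i], end(cgiGr)[i]) <- cseq
        }
    }
    genome <- DNAStringSet(seqs)
    names(genome) <- chroms

    if (is.null(geneDf)) {
        genes <- GRanges(seqinfo = si)
        mcols(genes)$gene_id <- character(0)
        mcols(genes)$tss <- integer(0)
        exons <- GRangesList()
    } else {
        genes <- GRanges(geneDf$chrom,
            IRanges(geneDf$start, geneDf$end),
            strand = geneDf$strand, seqinfo = si
        )
        mcols(genes)$gene_id <- geneDf$gene_id
        mcols(genes)$tss <- geneDf$tss
        names(genes) <- geneDf$gene_id
        exons <- .defaultExons(genes)
    }
    new("SimGenome",
        genome = genome, genes = genes, exons = exons,
        cgi = cgiGr, repeats = repGr
    )
}

## two exons (5' 400 bp, 3' 600 bp) when the span allows, else one exon
.defaultExons <- function(genes) {
    exl <- lapply(seq_along(genes), function(i) {
        st <- start(genes)[i]
        en <- end(genes)[i]
        w <- en - st + 1L
        if (w >= 1200L) {
            ir <- IRanges(c(st, en - 599L), c(st + 399L, en))
        } else {
            ir <- IRanges(st, en)
        }
        GRanges(seqnames(genes)[i], ir,
            strand = strand(genes)[i],
            seqinfo = seqinfo(genes)
        )
    })
    names(exl) <- mcols(genes)$gene_id
    GRangesList(exl)
}

#' Partition a simulated genome into uniform-methylation regions
#'
#' CpG islands form their own regions; the gaps between them are tiled into
#' \code{regionLength} bp chunks (terminal remainders kept). The result is a
#' disjoint partition covering every chromosome, the resolution at which
#' [simulateMethylomes()] assigns methylation levels.
#'
#' @param sim a [SimGenome-class] object.
#' @param regionLength region size in bp (multiple of the 500 bp window).
#' @return A [GenomicRanges::GRanges] partition with logical metadata column
#'   \code{in_cgi}.
#' @export
methylationRegions <- function(sim, regionLength = 3000L) {
    stopifnot(is(sim, "SimGenome"))
    regionLength <- as.integer(regionLength)
    stopifnot(regionLength >= 500L)
    si <- seqinfo(sim@genome)
    out <- list()
    for (chr in GenomeInfoDb::seqlevels(si)) {
        L <- GenomeInfoDb::seqlengths(si)[[chr]]
        cg <- ranges(sort(sim@cgi[seqnames(sim@cgi) == chr]))
        gaps <- setdiff(IRanges(1L, L), cg)
        tiles <- lapply(seq_along(gaps), function(i) {
            st <- seq(start(gaps)[i], end(gaps)[i], by = regionLength)
            IRanges(st, pmin(st + regionLength - 1L, end(gaps)[i]))
        })
        tiles <- if (length(tiles)) do.call(c, tiles) else IRanges()
        ir <- c(tiles, cg)
        flag <- c(
            rep(FALSE, length(tiles)),
            rep(TRUE, length(cg))
        )
        o <- order(start(ir))
        gr <- GRanges(chr, ir[o], seqinfo = si)
        mcols(gr)$in_cgi <- flag[o]
        out[[chr]] <- gr
    }
    unname(do.call(c, unname(out)))
}

#' Simulate two regional methylomes with planted DMRs
#'
#' Each region of the partition receives a methylation level shared by both
#' conditions (Beta-distributed around \code{methBackground}); exactly
#' \code{nDmrs} regions are planted as DMRs, alternating direction, with the
#' hypermethylated side at \code{methHigh} and the other at \code{methLow}.
#' Placement ("background", "cgi", "repeat" or "any") selects the candidate
#' pool; see [SimConfig()].
#'
#' Uses the RNG stream seeded with \code{config@seed + 1}.
#'
#' @param sim a [SimGenome-class] object.
#' @param config a [SimConfig-class] object.
#' @param regions optional region partition (default
#'   \code{methylationRegions(sim, config@regionLength)}).
#' @return A list with elements \code{methA}, \code{methB} (the regions with
#'   numeric metadata column \code{meth}) and \code{truth}, a data.frame with
#'   columns chrom, start, end (1-based inclusive), meth_A, meth_B, is_dmr
#'   and direction (\code{A_hyper}/\code{B_hyper}/\code{none}).
#' @export
simulateMethylomes <- function(sim, config, regions = NULL) {
    stopifnot(is(sim, "SimGenome"), is(config, "SimConfig"))
    validObject(config)
    if (is.null(regions)) {
        regions <- methylationRegions(sim, config@regionLength)
    }
    n <- length(regions)
    set.seed(config@seed + 1L)

    mb <- config@methBackground
    if (mb <= 0 || mb >= 1) {
        base <- rep(mb, n)
    } else {
        base <- rbeta(n, 10 * mb, 10 * (1 - mb))
    }
    methA <- methB <- base
    isDmr <- rep(FALSE, n)
    direction <- rep("none", n)

    if (config@nDmrs > 0L) {
        wide <- BiocGenerics::width(regions) >= 500L
        ## background DMRs are planted only on full-length blocks, so every
        ## planted region spans regionLength/500 windows
        full <- BiocGenerics::width(regions) >= config@regionLength
        cand <- switch(config@dmrPlacement,
            any = which(wide),
            cgi = which(wide & overlapsAny(regions, sim@cgi)),
            "repeat" = which(wide & overlapsAny(regions, sim@repeats)),
            background = {
                tssFlank <- GRanges(
                    seqnames(sim@genes),
                    IRanges(
                        pmax(1L, mcols(sim@genes)$tss - 5000L),
                        mcols(sim@genes)$tss + 5000L
                    ),
                    seqinfo = seqinfo(regions)
                )
                excl <- overlapsAny(regions, sim@cgi) |
                    overlapsAny(regions, sim@genes) |
                    overlapsAny(regions, sim@repeats) |
                    overlapsAny(regions, tssFlank)
                which(full & !excl)
            }
        )
        if (config@nDmrs > length(cand)) {
            stop(
                "cannot plant ", config@nDmrs, " DMRs: only ", length(cand),
                " eligible '", config@dmrPlacement, "' regions",
                call. = FALSE
            )
        }
        idx <- cand[sample.int(length(cand), config@nDmrs)]
        dirs <- rep(c("A_hyper", "B_hyper"), length.out = config@nDmrs)
        aHyper <- idx[dirs == "A_hyper"]
        bHyper <- idx[dirs == "B_hyper"]
        methA[aHyper] <- config@methHigh
        methB[aHyper] <- config@methLow
        methA[bHyper] <- config@methLow
        methB[bHyper] <- config@methHigh
        isDmr[idx] <- TRUE
        direction[idx] <- dirs
    }

    mkMeth <- function(v) {
        gr <- regions
        mcols(gr)$meth <- v
        gr
    }
    truth <- data.frame(
        chrom = as.character(seqnames(regions)),
        start = start(regions), end = end(regions),
        meth_A = methA, meth_B = methB,
        is_dmr = isDmr, direction = direction,
        stringsAsFactors = FALSE
    )
    list(methA = mkMeth(methA), methB = mkMeth(methB), truth = truth)
}

#' Simulate MBD-capture reads from a methylome
#'
#' Models methyl-CpG-binding-domain capture: a fragment of
#' \code{fragmentLength} bp starting at genomic position p is sampled with
#' probability proportional to (number of CpG dinucleotides in the fragment
#' x the regional methylation level at the fragment midpoint) + epsilon,
#' where epsilon is \code{samplingFloor} times the maximum raw weight
#' (low-salt carryover from unmethylated DNA). Each sampled fragment emits
#' one single-end read of \code{readLength} bp from a uniformly chosen end
#' (the 5' end of either strand), so every read lies inside its source
#' fragment.
#'
#' @param genome a [SimGenome-class] object or a
#'   [Biostrings::DNAStringSet].
#' @param methylome a [GenomicRanges::GRanges] partition with numeric
#'   metadata column \code{meth} covering the genome (from
#'   [simulateMethylomes()]).
#' @param config a [SimConfig-class] object.
#' @param seed RNG seed for this library; defaults to \code{config@seed + 2}
#'   (use \code{config@seed + 3} for the second library to keep streams
#'   disjoint).
#' @return A [GenomicRanges::GRanges] of exactly
#'   \code{config@readsPerLibrary} stranded read intervals.
#' @export
simulateCaptureReads <- function(genome, methylome, config,
                                 seed = config@seed + 2L) {
    stopifnot(is(config, "SimConfig"))
    if (is(genome, "SimGenome")) genome <- genome@genome
    stopifnot(is(genome, "DNAStringSet"))
    if (!"meth" %in% colnames(mcols(methylome))) {
        stop("methylome must carry a 'meth' metadata column")
    }
    FL <- config@fragmentLength
    RL <- config@readLength
    nReads <- config@readsPerLibrary
    chroms <- names(genome)
    si <- GenomeInfoDb::Seqinfo(chroms, Biostrings::width(genome))
    empty <- GRanges(seqinfo = si)
    if (nReads == 0L) {
        return(empty)
    }

    weights <- vector("list", length(chroms))
    names(weights) <- chroms
    for (chr in chroms) {
        s <- genome[[chr]]
        L <- length(s)
        if (L < FL) {
            weights[[chr]] <- numeric(0)
            next
        }
        nPos <- L - FL + 1L
        cgStart <- start(matchPattern("CG", s))
        cs <- c(0L, cumsum(tabulate(cgStart, nbins = L)))
        pos <- seq_len(nPos)
        nCpG <- cs[pos + FL - 1L] - cs[pos] # CG starts in [p, p+FL-2]
        mids <- pos + FL %/% 2L
        reg <- methylome[seqnames(methylome) == chr]
        reg <- reg[order(start(reg))]
        if (length(reg) == 0L) {
            stop("methylome has no regions on ", chr)
        }
        k <- findInterval(mids, start(reg))
        if (any(k < 1L) || any(mids > end(reg)[k])) {
            stop("methylome does not cover ", chr)
        }
        weights[[chr]] <- nCpG * mcols(reg)$meth[k]
    }
    maxw <- suppressWarnings(max(vapply(
        weights,
        function(w) if (length(w)) max(w) else 0, numeric(1)
    )))
    if (!is.finite(maxw) || maxw <= 0) {
        stop(
            "degenerate sampling weights: no methylated CpG mass anywhere ",
            "in the genome",
            call. = FALSE
        )
    }
    eps <- config@samplingFloor * maxw
    totW <- vapply(
        weights,
        function(w) sum(w) + length(w) * eps, numeric(1)
    )
    if (sum(totW) <= 0) {
        stop("degenerate sampling weights: total weight is zero",
            call. = FALSE
        )
    }

    set.seed(seed)
    perChrom <- as.vector(rmultinom(1L, nReads, totW))
    out <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
        cnt <- perChrom[i]
        if (cnt == 0L) {
            out[[i]] <- empty
            next
        }
        w <- weights[[chroms[i]]] + eps
        fragStart <- sample.int(length(w), cnt, replace = TRUE, prob = w)
        minus <- runif(cnt) < 0.5
        readStart <- ifelse(minus, fragStart + FL - RL, fragStart)
        gr <- GRanges(chroms[i],
            IRanges(readStart, width = RL),
            strand = ifelse(minus, "-", "+"),
            seqinfo = si
        )
        out[[i]] <- gr
    }
    reads <- unname(do.call(c, out))
    names(reads) <- sprintf("read%06d", seq_along(reads))
    reads
}
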