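## Genomic-feature annotation of DMRs, TSS association within +/-5 kb, and
## CpG observed/expected profiling of the 500 bp window around each DMR.

#' Strand-aware promoter intervals
#'
#' The promoter of a gene is the \code{width} bp immediately upstream of its
#' TSS on the annotated strand (the TSS itself excluded), truncated at
#' chromosome starts.
#'
#' @param genes a [GenomicRanges::GRanges] with metadata column \code{tss}.
#' @param width promoter width in bp (default 5000).
#' @return A [GenomicRanges::GRanges] parallel to \code{genes}.
#' @export
promoterRegions <- function(genes, width = 5000L) {
    if (length(genes) == 0L) {
        return(granges(genes))
    }
    tss <- mcols(genes)$tss
    plus <- as.character(strand(genes)) == "+"
    st <- ifelse(plus, tss - width, tss + 1L)
    en <- ifelse(plus, tss - 1L, tss + width)
    st <- pmax(st, 1L)
    gr <- GRanges(seqnames(genes), IRanges(st, en),
        strand = strand(genes),
        seqinfo = seqinfo(genes)
    )
    names(gr) <- names(genes)
    gr
}

#' Assign each DMR one genomic-feature category
#'
#' Any-overlap classification under a configurable precedence (default
#' promoter > exon > intron > repeat > intergenic, favouring the regulatory
#' interpretation); every DMR gets exactly one category. Promoters are the
#' 5 kb strand-aware upstream of each TSS; introns are gene spans minus
#' exons.
#'
#' @param dmrs [GenomicRanges::GRanges] of DMR windows.
#' @param genes gene spans with \code{tss} metadata (see [readGeneTable()]).
#' @param exons a [GenomicRanges::GRangesList] of exons per gene.
#' @param repeats the repeat track.
#' @param precedence category order, a permutation of
#'   c("promoter", "exon", "intron", "repeat").
#' @param promoterWidth promoter width in bp.
#' @return A factor with levels promoter, exon, intron, repeat, intergenic.
#' @export
assignFeature <- function(dmrs, genes, exons, repeats,
                          precedence = c(
                              "promoter", "exon", "intron",
                              "repeat"
                          ),
                          promoterWidth = 5000L) {
    stopifnot(setequal(precedence, c("promoter", "exon", "intron", "repeat")))
    exonGr <- unlist(exons, use.names = FALSE)
    intronGr <- if (length(genes)) {
        unlist(psetdiff(granges(genes), exons), use.names = FALSE)
    } else {
        GRanges()
    }
    tracks <- list(
        promoter = promoterRegions(genes, promoterWidth),
        exon = exonGr,
        intron = intronGr,
        "repeat" = repeats
    )
    lv <- c(precedence, "intergenic")
    out <- rep("intergenic", length(dmrs))
    for (cat in rev(precedence)) {
        out[overlapsAny(dmrs, tracks[[cat]], ignore.strand = TRUE)] <- cat
    }
    factor(out, levels = lv)
}

#' Associate DMRs with genes by TSS proximity
#'
#' Reports every gene whose TSS lies within \code{flank} bp of a DMR (or
#' inside it). The relation is \code{overlapStart} when the DMR contains the
#' TSS, otherwise \code{upstream}/\code{downstream} by the strand-aware side
#' of the DMR relative to the gene. Distances are signed gaps from the TSS
#' to the nearest DMR edge, negative upstream of the TSS on the gene strand.
#'
#' @param dmrs [GenomicRanges::GRanges] of DMR windows.
#' @param genes gene spans with \code{gene_id} and \code{tss} metadata.
#' @param flank maximum TSS distance in bp (default 5000).
#' @return A data.frame with one row per (DMR, gene) pair: \code{dmr} (index
#'   into \code{dmrs}), \code{gene_id}, \code{relation},
#'   \code{distance_to_tss}.
#' @export
associateGenes <- function(dmrs, genes, flank = 5000L) {
    empty <- data.frame(
        dmr = integer(0), gene_id = character(0),
        relation = character(0), distance_to_tss = integer(0),
        stringsAsFactors = FALSE
    )
    if (length(dmrs) == 0L || length(genes) == 0L) {
        return(empty)
    }
    tss <- mcols(genes)$tss
    tssGr <- GRanges(seqnames(genes), IRanges(tss, width = 1L))
    near <- GRanges(
        seqnames(tssGr),
        IRanges(pmax(1L, tss - flank), tss + flank)
    )
    hits <- findOverlaps(dmrs, near, ignore.strand = TRUE)
    if (length(hits) == 0L) {
        return(empty)
    }
    qi <- queryHits(hits)
    si <- subjectHits(hits)
    dmrStart <- start(dmrs)[qi]
    dmrEnd <- end(dmrs)[qi]
    gTss <- tss[si]
    minusStrand <- as.character(strand(genes))[si] == "-"
    contains <- dmrStart <= gTss & gTss <= dmrEnd
    ## signed genomic gap from TSS to the nearest DMR edge
    gap <- ifelse(contains, 0L,
        ifelse(dmrEnd < gTss, dmrEnd - gTss, dmrStart - gTss)
    )
    ## negative = upstream of the TSS on the gene strand
    dist <- ifelse(minusStrand, -gap, gap)
    relation <- ifelse(contains, "overlapStart",
        ifelse(dist < 0, "upstream", "downstream")
    )
    data.frame(
        dmr = qi,
        gene_id = mcols(genes)$gene_id[si],
        relation = relation,
        distance_to_tss = as.integer(dist),
        stringsAsFactors = FALSE
    )
}

#' CpG observed/expected ratio of DNA sequences
#'
#' For each sequence: \code{oe = n_CpG x L / (n_C x n_G)}, with
#' \code{n_CpG} the count of CG dinucleotides, \code{n_C}/\code{n_G} the C
#' and G mononucleotide counts (N bases contribute to neither and break
#' dinucleotides) and L the sequence length. Sequences with no C or no G
#' give an undefined (NA) ratio flagged in \code{defined}.
#'
#' @param seqs a [Biostrings::DNAStringSet], [Biostrings::DNAString] or
#'   character vector of A/C/G/T/N sequences.
#' @return A data.frame with columns n_cpg, n_c, n_g, length, oe, defined.
#' @examples
#' cpgOE(c("ACGT", "AATT")) # oe 4 and undefined
#' @export
cpgOE <- function(seqs) {
    if (is.character(seqs)) seqs <- DNAStringSet(toupper(seqs))
    if (is(seqs, "DNAString")) seqs <- DNAStringSet(seqs)
    stopifnot(is(seqs, "DNAStringSet"))
    if (any(Biostrings::width(seqs) < 2L)) {
        stop("sequences must have length >= 2")
    }
    nCpG <- vcountPattern("CG", seqs)
    freq <- letterFrequency(seqs, c("C", "G"))
    len <- Biostrings::width(seqs)
    nC <- freq[, "C"]
    nG <- freq[, "G"]
    defined <- nC > 0 & nG > 0
    oe <- ifelse(defined, nCpG * len / (nC * nG), NA_real_)
    data.frame(
        n_cpg = nCpG, n_c = nC, n_g = nG, length = len,
        oe = oe, defined = defined
    )
}

## extract genomic sequence for intervals from a DNAStringSet genome
.extractRegions <- function(genome, gr) {
    chrom <- as.character(seqnames(gr))
    seqs <- vapply(seq_along(gr), function(i) {
        as.character(subseq(genome[[chrom[i]]], start(gr)[i], end(gr)[i]))
    }, character(1))
    DNAStringSet(seqs)
}

#' CpG o/e of DMR neighbourhoods, stratified by feature category
#'
#' Computes the CpG observed/expected ratio of the \code{windowSize} bp
#' window centred on each DMR midpoint (equal to the DMR window itself for
#' standard tiles), clipped at chromosome ends, and summarizes the
#' distribution per feature category: median o/e, the fraction above 0.6
#' (the conventional CGI threshold, reported descriptively, never used as a
#' filter) and counts.
#'
#' @param dmrs [GenomicRanges::GRanges] of DMR windows.
#' @param genome a [Biostrings::DNAStringSet] or [SimGenome-class].
#' @param categories factor from [assignFeature()] (parallel to
#'   \code{dmrs}).
#' @param windowSize neighbourhood width in bp (default 500).
#' @return A list: \code{perDmr} (data.frame with the per-DMR
#'   [cpgOE()] columns plus \code{category}) and \code{summary} (per
#'   category: n, n_defined, median_oe, frac_above_0.6).
#' @export
stratifyOE <- function(dmrs, genome, categories, windowSize = 500L) {
    if (is(genome, "SimGenome")) genome <- genome@genome
    stopifnot(is(genome, "DNAStringSet"))
    stopifnot(length(categories) == length(dmrs))
    categories <- as.factor(categories)
    if (length(dmrs) == 0L) {
        perDmr <- cbind(
            cpgOE(DNAStringSet()),
            category = factor(character(0), levels = levels(categories))
        )
        return(list(perDmr = perDmr, summary = data.frame(
            category = character(0), n = integer(0), n_defined = integer(0),
            median_oe = numeric(0), frac_above_0.6 = numeric(0)
        )))
    }
    lens <- setNames(Biostrings::width(genome), names(genome))
    mid <- (start(dmrs) + end(dmrs)) %/% 2L
    half <- windowSize %/% 2L
    st <- pmax(1L, mid - half + 1L)
    en <- pmin(lens[as.character(seqnames(dmrs))], mid + half)
    win <- GRanges(seqnames(dmrs), IRanges(st, unname(en)))
    perDmr <- cpgOE(.extractRegions(genome, win))
    perDmr$category <- categories
    lv <- levels(categories)
    summary <- do.call(rbind, lapply(lv, function(cat) {
        sub <- perDmr[perDmr$category == cat & perDmr$defined, , drop = FALSE]
        data.frame(
            category = cat,
            n = sum(perDmr$category == cat),
            n_defined = nrow(sub),
            median_oe = if (nrow(sub)) median(sub$oe) else NA_real_,
            frac_above_0.6 = if (nrow(sub)) mean(sub$oe > 0.6) else NA_real_
        )
    }))
    list(perDmr = perDmr, summary = summary)
}

#' Annotate called DMRs in place
#'
#' Convenience wrapper adding the feature category, associated genes
#' (within \code{flank} of the TSS, comma-joined with relations and
#' distances) and the 500 bp CpG o/e to the metadata of a DMR set.
#'
#' @param dmrs [GenomicRanges::GRanges] from [callDmrs()].
#' @param genes,exons,repeats annotation tracks (see [assignFeature()]).
#' @param genome sequence source for CpG o/e.
#' @param flank TSS association distance (default 5000).
#' @return \code{dmrs} with metadata columns \code{category}, \code{genes},
#'   \code{relations}, \code{distances_to_tss}, \code{cpg_oe}.
#' @export
annotateDmrs <- function(dmrs, genes, exons, repeats, genome,
                         flank = 5000L) {
    category <- assignFeature(dmrs, genes, exons, repeats)
    assoc <- associateGenes(dmrs, genes, flank = flank)
    collapse <- function(v, i) {
        paste(v[assoc$dmr == i], collapse = ",")
    }
    oe <- stratifyOE(dmrs, genome, category)$perDmr$oe
    mcols(dmrs)$category <- category
    mcols(dmrs)$genes <- vapply(
        seq_along(dmrs),
        function(i) collapse(assoc$gene_id, i), character(1)
    )
    mcols(dmrs)$relations <- vapply(
        seq_along(dmrs),
        function(i) collapse(assoc$relation, i), character(1)
    )
    mcols(dmrs)$distances_to_tss <- vapply(
        seq_along(dmrs),
        function(i) collapse(assoc$distance_to_tss, i), character(1)
    )
    mcols(dmrs)$cpg_oe <- if (length(dmrs)) oe else numeric(0)
    dmrs
}
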