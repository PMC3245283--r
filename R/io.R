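## Readers/writers for every on-disk format the pipeline touches.
##
## Coordinate conventions: in memory everything is a 1-based inclusive
## GRanges. BED files are 0-based half-open on disk and the BED reader/writer
## is the only place that conversion happens; report tables (genes, truth,
## windows, DMRs) are printed 1-based inclusive, matching the published
## 500 bp tiles that start at 1 mod 500.

.openHeader <- function(what, extra = character()) {
    c(
        sprintf(
            "# %s table written by MethCapDMR %s; coordinates 1-based inclusive",
            what, as.character(packageVersion("MethCapDMR"))
        ),
        extra
    )
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3 to 6 tab-separated columns (chrom, start, end, name, score,
#' strand). BED coordinates are 0-based half-open on disk and converted to
#' the package's 1-based inclusive GRanges on read. Malformed lines are
#' rejected with their line numbers. A missing or "." strand is treated as
#' "+" (window counting is strand-blind anyway).
#'
#' @param path file path.
#' @param genome optional [Biostrings::DNAStringSet] or named integer vector
#'   of chromosome lengths; when supplied, intervals on unknown chromosomes
#'   or beyond chromosome ends are errors.
#' @return A [GenomicRanges::GRanges]; empty files give an empty object.
#' @export
readBed <- function(path, genome = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lineNo <- seq_along(lines)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) &
        nzchar(trimws(lines))
    lines <- lines[keep]
    lineNo <- lineNo[keep]
    if (!length(lines)) {
        return(GRanges())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- nf < 3L | nf > 6L
    if (any(bad)) {
        stop(
            "BED parse error: expected 3-6 tab-separated columns at line(s) ",
            paste(head(lineNo[bad], 5L), collapse = ", ")
        )
    }
    getCol <- function(i) {
        vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
            character(1)
        )
    }
    chrom <- getCol(1L)
    start0 <- suppressWarnings(as.numeric(getCol(2L)))
    end0 <- suppressWarnings(as.numeric(getCol(3L)))
    bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
    if (any(bad)) {
        stop(
            "BED parse error: invalid interval (need 0 <= start < end) at ",
            "line(s) ", paste(head(lineNo[bad], 5L), collapse = ", ")
        )
    }
    strand <- getCol(6L)
    strand[is.na(strand) | strand == "."] <- "+"
    bad <- !strand %in% c("+", "-")
    if (any(bad)) {
        stop(
            "BED parse error: invalid strand at line(s) ",
            paste(head(lineNo[bad], 5L), collapse = ", ")
        )
    }
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
    nm <- getCol(4L)
    if (!all(is.na(nm))) names(gr) <- nm
    if (!is.null(genome)) {
        lens <- if (is(genome, "DNAStringSet")) {
            setNames(Biostrings::width(genome), names(genome))
        } else {
            genome
        }
        unknown <- !chrom %in% names(lens)
        if (any(unknown)) {
            stop(
                "BED intervals on unknown chromosome(s): ",
                paste(unique(chrom[unknown]), collapse = ", ")
            )
        }
        over <- end(gr) > lens[chrom]
        if (any(over)) {
            stop(
                "BED intervals beyond chromosome end at line(s) ",
                paste(head(lineNo[over], 5L), collapse = ", ")
            )
        }
        GenomeInfoDb::seqlevels(gr) <- names(lens)
        GenomeInfoDb::seqlengths(gr) <- unname(lens)
    }
    gr
}

#' Write intervals as BED6
#'
#' Converts the 1-based inclusive GRanges to BED's 0-based half-open
#' coordinates. Score is 0; names come from \code{names(x)} (or "." when
#' absent); "*" strand is written as "+".
#'
#' @param x a [GenomicRanges::GRanges].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path) {
    strand <- as.character(strand(x))
    strand[strand == "*"] <- "+"
    nm <- names(x)
    if (is.null(nm)) nm <- rep(".", length(x))
    df <- data.frame(
        chrom = as.character(seqnames(x)),
        start = format(start(x) - 1L, scientific = FALSE, trim = TRUE),
        end = format(end(x), scientific = FALSE, trim = TRUE),
        name = nm, score = 0L, strand = strand
    )
    write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased and record names truncated at the first
#' whitespace. Duplicate names are an error.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastaGenome <- function(path) {
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x))) {
        stop(
            "duplicate sequence names in ", path, ": ",
            paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")
        )
    }
    DNAStringSet(toupper(as.character(x)))
}

#' Write a genome FASTA (60-column wrapped)
#' @param x a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaGenome <- function(x, path) {
    writeXStringSet(x, path, width = 60L)
    invisible(path)
}

#' Read/write the gene-model table
#'
#' Tab-separated columns: gene_id, chrom, strand, tss, tx_start, tx_end,
#' exon_starts, exon_ends (exon lists comma-separated; all coordinates
#' 1-based inclusive). The TSS must equal the 5' end of the span on the
#' annotated strand and exons must be disjoint, sorted and inside the span.
#'
#' @param path file path.
#' @return \code{readGeneTable}: a list with \code{genes} (a
#'   [GenomicRanges::GRanges] with \code{gene_id} and \code{tss} metadata)
#'   and \code{exons} (a [GenomicRanges::GRangesList], one element per gene).
#' @export
readGeneTable <- function(path) {
    df <- read.table(path,
        header = TRUE, sep = "\t", comment.char = "#",
        stringsAsFactors = FALSE
    )
    need <- c(
        "gene_id", "chrom", "strand", "tss", "tx_start", "tx_end",
        "exon_starts", "exon_ends"
    )
    if (!all(need %in% colnames(df))) {
        stop(
            "gene table missing column(s): ",
            paste(setdiff(need, colnames(df)), collapse = ", ")
        )
    }
    if (!all(df$strand %in% c("+", "-"))) {
        stop("gene strands must be '+' or '-'")
    }
    fivePrime <- ifelse(df$strand == "+", df$tx_start, df$tx_end)
    if (!all(df$tss == fivePrime)) {
        stop(
            "tss must equal the 5' end of the span for gene(s): ",
            paste(df$gene_id[df$tss != fivePrime], collapse = ", ")
        )
    }
    genes <- GRanges(df$chrom, IRanges(df$tx_start, df$tx_end),
        strand = df$strand
    )
    mcols(genes)$gene_id <- df$gene_id
    mcols(genes)$tss <- as.integer(df$tss)
    names(genes) <- df$gene_id
    exl <- lapply(seq_len(nrow(df)), function(i) {
        st <- as.integer(strsplit(df$exon_starts[i], ",")[[1]])
        en <- as.integer(strsplit(df$exon_ends[i], ",")[[1]])
        if (length(st) != length(en) || any(is.na(st)) || any(is.na(en))) {
            stop("malformed exon lists for gene ", df$gene_id[i])
        }
        if (is.unsorted(st, strictly = TRUE) || any(en < st) ||
            any(st[-1] <= en[-length(en)]) ||
            min(st) < df$tx_start[i] || max(en) > df$tx_end[i]) {
            stop(
                "exons must be disjoint, sorted and within the span for ",
                "gene ", df$gene_id[i]
            )
        }
        GRanges(df$chrom[i], IRanges(st, en), strand = df$strand[i])
    })
    names(exl) <- df$gene_id
    list(genes = genes, exons = GRangesList(exl))
}

#' @param genes a [GenomicRanges::GRanges] with \code{gene_id} and \code{tss}.
#' @param exons a [GenomicRanges::GRangesList] parallel to \code{genes}.
#' @rdname readGeneTable
#' @export
writeGeneTable <- function(genes, exons, path) {
    joined <- function(f) {
        vapply(
            seq_along(exons),
            function(i) paste(f(exons[[i]]), collapse = ","), character(1)
        )
    }
    df <- data.frame(
        gene_id = mcols(genes)$gene_id,
        chrom = as.character(seqnames(genes)),
        strand = as.character(strand(genes)),
        tss = mcols(genes)$tss,
        tx_start = start(genes), tx_end = end(genes),
        exon_starts = joined(start), exon_ends = joined(end)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.openHeader("gene model"), con)
    suppressWarnings(write.table(df, con,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
    ))
    invisible(path)
}

#' Read/write the simulator ground-truth table
#'
#' Columns: chrom, start, end (1-based inclusive), meth_A, meth_B, is_dmr,
#' direction.
#'
#' @param truth a data.frame as returned by [simulateMethylomes()].
#' @param path file path.
#' @return \code{readTruthTable}: the truth data.frame.
#' @export
writeTruthTable <- function(truth, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.openHeader("simulation ground truth"), con)
    suppressWarnings(write.table(truth, con,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
    ))
    invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
    read.table(path,
        header = TRUE, sep = "\t", comment.char = "#",
        stringsAsFactors = FALSE
    )
}

#' Write a DMR report table
#'
#' One row per called 500 bp window, in the layout of the published report
#' tables: 1-based inclusive coordinates, both rpm columns to two decimals,
#' the rpm ratio printed as \code{Inf} when the minor library has zero
#' reads, the exact-test p-value, an informational BH-adjusted column, and
#' the direction of hypermethylation. Annotation columns (category, genes,
#' relations, TSS distances, CpG o/e) are appended when present.
#'
#' @param dmrs a [GenomicRanges::GRanges] from [callDmrs()], optionally
#'   annotated by [annotateDmrs()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDmrTable <- function(dmrs, path) {
    mc <- mcols(dmrs)
    fmtRpm <- function(v) sprintf("%.2f", v)
    fmtRatio <- function(v) {
        ifelse(is.infinite(v), "Inf", sprintf("%.2f", v))
    }
    df <- data.frame(
        chrom = as.character(seqnames(dmrs)),
        start = start(dmrs), end = end(dmrs),
        rpm_A = fmtRpm(mc$rpm_A), rpm_B = fmtRpm(mc$rpm_B),
        ratio = fmtRatio(mc$ratio),
        p_value = sprintf("%.4g", mc$p_value),
        fdr = sprintf("%.4g", mc$fdr),
        direction = as.character(mc$direction),
        stringsAsFactors = FALSE
    )
    for (col in c(
        "category", "genes", "relations", "distances_to_tss",
        "cpg_oe"
    )) {
        if (col %in% colnames(mc)) {
            v <- mc[[col]]
            df[[col]] <- if (is.numeric(v)) sprintf("%.3f", v) else
                as.character(v)
        }
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.openHeader("DMR report", c(
        "# rpm = reads per million; ratio = max(rpm)/min(rpm), Inf when the",
        "# minor library has zero reads; distances negative upstream of the",
        "# TSS on the gene strand"
    )), con)
    suppressWarnings(write.table(df, con,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
    ))
    invisible(path)
}

#' @rdname writeDmrTable
#' @return \code{readDmrTable}: a [GenomicRanges::GRanges] with the report
#'   columns as metadata (\code{ratio} parsed back to numeric \code{Inf}).
#' @export
readDmrTable <- function(path) {
    df <- read.table(path,
        header = TRUE, sep = "\t", comment.char = "#",
        stringsAsFactors = FALSE
    )
    if (!nrow(df)) {
        return(GRanges())
    }
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    for (col in setdiff(colnames(df), c("chrom", "start", "end"))) {
        v <- df[[col]]
        if (col %in% c("rpm_A", "rpm_B", "ratio", "p_value", "fdr", "cpg_oe")) {
            v <- as.numeric(v)
        }
        mcols(gr)[[col]] <- v
    }
    gr
}

#' Read a one-gene-per-line list
#'
#' Empty lines and "#" comments are skipped; surrounding whitespace is
#' trimmed.
#'
#' @param path file path.
#' @return Character vector of gene identifiers.
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a two-column gene-to-term annotation table
#'
#' Tab-separated, no header required (a header line "gene\\tterm" is
#' tolerated); one row per gene/term pair.
#'
#' @param path file path.
#' @return A data.frame with columns \code{gene} and \code{term}.
#' @export
readTermMap <- function(path) {
    df <- read.table(path,
        header = FALSE, sep = "\t", comment.char = "#",
        stringsAsFactors = FALSE, col.names = c("gene", "term")
    )
    if (nrow(df) &&
        identical(unname(tolower(unlist(df[1, ]))), c("gene", "term"))) {
        df <- df[-1, , drop = FALSE]
    }
    df
}
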