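## one + strand and one - strand gene with identical geometry
.toyGenes <- function() {
    genes <- GRanges(
        c("chr1", "chr1"), IRanges(c(20001L, 50001L), c(24000L, 54000L)),
        strand = c("+", "-")
    )
    mcols(genes)$gene_id <- c("gplus", "gminus")
    mcols(genes)$tss <- c(20001L, 54000L)
    names(genes) <- mcols(genes)$gene_id
    exons <- GRangesList(
        gplus = GRanges("chr1", IRanges(c(20001L, 23401L), c(20400L, 24000L)),
            strand = "+"
        ),
        gminus = GRanges("chr1", IRanges(c(50001L, 53601L), c(50600L, 54000L)),
            strand = "-"
        )
    )
    list(genes = genes, exons = exons)
}

test_that("feature assignment is total, unique and precedence-ordered", {
    g <- .toyGenes()
    repeats <- GRanges("chr1", IRanges(c(23401L, 80001L), c(24400L, 81000L)))
    dmrs <- GRanges("chr1", IRanges(
        c(18001L, 23501L, 90001L, 21001L),
        width = 500L
    ))
    cat <- assignFeature(dmrs, g$genes, g$exons, repeats)
    ## 2 kb upstream of + TSS -> promoter; exon inside a repeat -> exon;
    ## nothing -> intergenic; gene body between exons -> intron
    expect_equal(
        as.character(cat),
        c("promoter", "exon", "intergenic", "intron")
    )
    expect_false(any(is.na(cat)))

    ## precedence is configurable
    cat2 <- assignFeature(dmrs, g$genes, g$exons, repeats,
        precedence = c("repeat", "exon", "intron", "promoter")
    )
    expect_equal(as.character(cat2)[2], "repeat")
})

test_that("TSS association is strand-aware with signed distances", {
    g <- .toyGenes()
    ## DMR containing the + TSS
    ov <- associateGenes(GRanges("chr1", IRanges(19751L, 20250L)), g$genes)
    expect_equal(ov$relation, "overlapStart")
    expect_equal(ov$distance_to_tss, 0L)

    ## 2 kb 5' of the + TSS -> upstream, negative distance
    up <- associateGenes(GRanges("chr1", IRanges(17501L, 18000L)), g$genes)
    expect_equal(up$relation, "upstream")
    expect_equal(up$distance_to_tss, -2001L)

    ## same geometry mirrored on the - strand gene: DMR right of the TSS
    upm <- associateGenes(GRanges("chr1", IRanges(56001L, 56500L)), g$genes)
    expect_equal(upm$gene_id, "gminus")
    expect_equal(upm$relation, "upstream")
    expect_equal(upm$distance_to_tss, -2001L)

    ## 3' side is downstream on each strand
    dn <- associateGenes(GRanges("chr1", IRanges(21001L, 21500L)), g$genes)
    expect_equal(dn$relation, "downstream")
    expect_true(dn$distance_to_tss > 0)

    ## beyond the 5 kb flank -> no association
    far <- associateGenes(GRanges("chr1", IRanges(26001L, 26500L)), g$genes)
    expect_equal(nrow(far), 0L)
})

test_that("CpG o/e follows its formula and matches a naive recount", {
    r <- cpgOE("ACGT")
    expect_equal(r$n_cpg, 1L)
    expect_equal(r$oe, 4)

    r2 <- cpgOE("AATT")
    expect_false(r2$defined)
    expect_true(is.na(r2$oe))

    ## N bases break dinucleotides and are excluded from n_C/n_G
    r3 <- cpgOE("ACNGT")
    expect_equal(r3$n_cpg, 0L)
    expect_equal(r3$n_c, 1L)
    expect_equal(r3$n_g, 1L)

    expect_error(cpgOE("A"), "length")

    set.seed(42)
    seqs <- vapply(1:200, function(i) {
        paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    }, character(1))
    expect_equal(cpgOE(seqs)$oe, vapply(seqs, naiveOE, numeric(1),
        USE.NAMES = FALSE
    ))
})

test_that("o/e stratification separates CGI-planted from background DMRs", {
    runOne <- function(placement, nDmrs) {
        cfg <- SimConfig(seed = 42L, dmrPlacement = placement, nDmrs = nDmrs)
        sim <- simulateGenome(cfg)
        meth <- simulateMethylomes(sim, cfg)
        tr <- meth$truth[meth$truth$is_dmr, ]
        planted <- GRanges(tr$chrom, IRanges(tr$start, tr$end))
        win <- tileGenomeWindows(sim)
        dmrWin <- win[overlapsAny(win, planted)]
        cats <- assignFeature(dmrWin, sim@genes, sim@exons, sim@repeats)
        stratifyOE(dmrWin, sim, cats)$summary
    }
    cgi <- runOne("cgi", 16L)
    expect_gt(cgi$median_oe[cgi$category == "promoter"], 0.6)
    bg <- runOne("background", 10L)
    expect_lt(bg$median_oe[bg$category == "intergenic"], 0.6)

    ## empty DMR list is not an error
    cfg <- tinyConfig()
    sim <- simulateGenome(cfg)
    empty <- stratifyOE(
        GRanges(), sim,
        factor(character(0), levels = "promoter")
    )
    expect_equal(nrow(empty$perDmr), 0L)
})
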