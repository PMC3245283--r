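test_that("simulated genome realizes its CpG o/e targets and structure", {
    ## 10 CGIs of 1 kb on a 200 kb chromosome
    cfg <- SimConfig(
        seed = 1L, nChroms = 1L, chromLength = 200000L,
        nGenes = 10L, nCgis = 10L, nRepeats = 0L, nDmrs = 0L
    )
    sim <- simulateGenome(cfg)
    expect_equal(length(sim@cgi), 10L)
    expect_true(all(width(sim@cgi) == 1000L))
    expect_true(all(end(sim@cgi) <= 200000L & start(sim@cgi) >= 1L))

    oeCgi <- cpgOE(MethCapDMR:::.extractRegions(sim@genome, sim@cgi))$oe
    expect_gt(mean(oeCgi), 0.75)
    expect_lt(mean(oeCgi), 1.05)

    tiles <- tileGenomeWindows(sim, 1000L)
    bg <- tiles[!overlapsAny(tiles, sim@cgi + 500L)]
    oeBg <- cpgOE(MethCapDMR:::.extractRegions(sim@genome, bg))$oe
    expect_lt(abs(mean(oeBg, na.rm = TRUE) - cfg@backgroundOE), 0.15)
    ## CGI vs background separation reproduces the stratified o/e contrast
    expect_gt(mean(oeCgi) - mean(oeBg, na.rm = TRUE), 0.3)

    ## strand-aware TSS at the 5' end of each span
    plus <- as.character(strand(sim@genes)) == "+"
    expect_equal(
        mcols(sim@genes)$tss,
        ifelse(plus, start(sim@genes), end(sim@genes))
    )
})

test_that("empty feature tracks and capacity errors behave as specified", {
    cfg <- SimConfig(
        seed = 3L, nChroms = 1L, chromLength = 60000L,
        nGenes = 2L, nCgis = 0L, nRepeats = 0L, nDmrs = 0L
    )
    sim <- simulateGenome(cfg)
    expect_equal(length(sim@cgi), 0L)
    expect_equal(length(sim@genome), 1L)
    expect_equal(length(sim@genome[[1]]), 60000L)

    over <- SimConfig(
        seed = 1L, nChroms = 1L, chromLength = 50000L,
        nGenes = 40L, nCgis = 0L, nRepeats = 0L
    )
    expect_error(simulateGenome(over), "capacity")
})

test_that("identical seeds give byte-identical genomes, reads and truth", {
    cfg <- tinyConfig()
    s1 <- simulateGenome(cfg)
    s2 <- simulateGenome(cfg)
    expect_identical(
        as.character(s1@genome),
        as.character(s2@genome)
    )
    m1 <- simulateMethylomes(s1, cfg)
    m2 <- simulateMethylomes(s2, cfg)
    expect_identical(m1$truth, m2$truth)
    r1 <- simulateCaptureReads(s1, m1$methA, cfg)
    r2 <- simulateCaptureReads(s2, m2$methA, cfg)
    expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("methylomes plant the configured DMRs over a covering partition", {
    cfg <- SimConfig(seed = 11L)
    sim <- simulateGenome(cfg)
    regions <- methylationRegions(sim, cfg@regionLength)
    ## disjoint partition covering the genome
    expect_equal(
        sum(width(regions)),
        sum(width(sim@genome))
    )
    expect_true(all(width(GenomicRanges::reduce(regions)) > 0))
    expect_equal(sum(width(GenomicRanges::reduce(regions))),
        sum(width(regions)))

    meth <- simulateMethylomes(sim, cfg, regions)
    tr <- meth$truth
    expect_equal(sum(tr$is_dmr), cfg@nDmrs)
    ## direction split approximately even
    expect_lte(abs(sum(tr$direction == "A_hyper") -
        sum(tr$direction == "B_hyper")), 1L)
    ## planted effect is exactly methHigh - methLow
    expect_true(all(abs(tr$meth_A[tr$is_dmr] - tr$meth_B[tr$is_dmr]) ==
        cfg@methHigh - cfg@methLow))
    expect_true(all(tr$meth_A >= 0 & tr$meth_A <= 1))
    expect_true(all(tr$meth_B >= 0 & tr$meth_B <= 1))
    ## non-DMR regions share one level, centred on the background mean
    bg <- tr[!tr$is_dmr, ]
    expect_identical(bg$meth_A, bg$meth_B)
    expect_gte(nrow(bg), 100L)
    expect_lt(abs(mean(bg$meth_A) - cfg@methBackground), 0.1)
})

test_that("null contrast and over-planting edge cases", {
    cfg <- tinyConfig(nDmrs = 0L)
    sim <- simulateGenome(cfg)
    meth <- simulateMethylomes(sim, cfg)
    expect_identical(meth$truth$meth_A, meth$truth$meth_B)
    expect_false(any(meth$truth$is_dmr))

    expect_error(
        simulateMethylomes(sim, tinyConfig(nDmrs = 500L)),
        "eligible"
    )
})

test_that("capture reads conserve counts, stay in bounds and honour zero", {
    cfg <- tinyConfig()
    sim <- simulateGenome(cfg)
    meth <- simulateMethylomes(sim, cfg)
    reads <- simulateCaptureReads(sim, meth$methA, cfg)
    expect_equal(length(reads), cfg@readsPerLibrary)
    expect_true(all(width(reads) == cfg@readLength))
    expect_true(all(start(reads) >= 1L))
    expect_true(all(end(reads) <= cfg@chromLength))

    none <- tinyConfig(readsPerLibrary = 0L)
    expect_equal(length(simulateCaptureReads(sim, meth$methA, none)), 0L)
})

test_that("a CpG-free genome gives a degenerate-weights error", {
    genome <- DNAStringSet(c(chr1 = strrep("AT", 1000L)))
    meth <- GRanges("chr1", IRanges(1L, 2000L))
    mcols(meth)$meth <- 1
    expect_error(
        simulateCaptureReads(genome, meth, tinyConfig()),
        "degenerate"
    )
})

test_that("read sampling follows the methylated-CpG weight model", {
    ## periodic sequence: exactly one CpG every 4 bp, so CpG density is
    ## uniform and all weight structure comes from methylation
    genome <- DNAStringSet(c(chr1 = strrep("ACGT", 12500L)))
    cfg <- tinyConfig(readsPerLibrary = 100000L, seed = 5L)

    ## uniform methylation: read starts approximately uniform
    flat <- GRanges("chr1", IRanges(1L, 50000L))
    mcols(flat)$meth <- 1
    reads <- simulateCaptureReads(genome, flat, cfg)
    win <- tileGenomeWindows(c(chr1 = 50000L))
    counts <- countOverlaps(win, MethCapDMR:::.readAnchors(reads))
    interior <- counts[3:(length(counts) - 2L)]
    gof <- suppressWarnings(stats::chisq.test(interior))
    expect_gt(gof$p.value, 0.01)

    ## hot region 0.9 vs background 0.05: ~18x density within a factor 1.5
    hot <- GRanges("chr1", IRanges(c(1L, 20001L, 25001L),
        c(20000L, 25000L, 50000L)
    ))
    mcols(hot)$meth <- c(0.05, 0.9, 0.05)
    reads <- simulateCaptureReads(genome, hot, cfg, seed = 9L)
    anchors <- MethCapDMR:::.readAnchors(reads)
    dens <- function(gr) {
        sum(overlapsAny(anchors, gr)) / sum(width(gr))
    }
    ratio <- dens(GRanges("chr1", IRanges(21001L, 24000L))) /
        dens(GRanges("chr1", IRanges(2000L, 18000L)))
    expect_gt(ratio, 18 / 1.5)
    expect_lt(ratio, 18 * 1.5)
})
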