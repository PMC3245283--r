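test_that("genome tiling follows the fixed 500 bp scheme", {
    w <- tileGenomeWindows(c(chr1 = 1500L))
    expect_equal(length(w), 3L)
    expect_equal(start(w), c(1L, 501L, 1001L))
    expect_equal(end(w), c(500L, 1000L, 1500L))

    ## terminal partial tile kept
    w <- tileGenomeWindows(c(chr1 = 1250L))
    expect_equal(length(w), 3L)
    expect_equal(width(w)[3], 250L)

    ## consecutive tiles print as consecutive 1-based 500 bp rows
    w <- tileGenomeWindows(c(chr12 = 5000L))
    expect_equal(start(w), seq(1L, 4501L, by = 500L))
    expect_equal(start(w)[-1] - end(w)[-length(w)], rep(1L, 9L))

    expect_error(tileGenomeWindows(c(chr1 = 100L), 0L), "positive")
})

test_that("read counting assigns by leftmost coordinate and conserves reads", {
    win <- tileGenomeWindows(c(chr1 = 2000L))
    ## boundary read starting at the last base of a tile
    reads <- GRanges("chr1", IRanges(500L, 535L), strand = "+")
    wc <- countWindowReads(win, reads, reads[0])
    expect_equal(assay(wc, "counts")[, "A"], c(1L, 0L, 0L, 0L))

    ## no reads -> all zero
    wc0 <- countWindowReads(win, reads[0], reads[0])
    expect_true(all(assay(wc0, "counts") == 0L))

    ## random reads match a brute-force double loop, and totals conserve
    set.seed(123)
    n <- 1000L
    st <- sample.int(1960L, n, replace = TRUE)
    rnd <- GRanges("chr1", IRanges(st, width = 36L),
        strand = sample(c("+", "-"), n, TRUE)
    )
    wc <- countWindowReads(win, rnd, rnd)
    brute <- vapply(seq_along(win), function(i) {
        sum(st >= start(win)[i] & st <= end(win)[i])
    }, integer(1))
    expect_equal(unname(assay(wc, "counts")[, "A"]), brute)
    expect_equal(
        sum(assay(wc, "counts")[, "A"]) + unplacedReads(wc)[["A"]],
        n
    )

    ## reads on unknown chromosomes land in the unplaced bucket
    stray <- GRanges(c("chr1", "chrUn"), IRanges(c(1L, 1L), width = 36L))
    GenomeInfoDb::seqlevels(stray) <- c("chr1", "chrUn")
    wcu <- countWindowReads(win, stray, stray[0])
    expect_equal(unplacedReads(wcu)[["A"]], 1L)
    expect_equal(sum(assay(wcu, "counts")[, "A"]), 1L)

    ## dedup removes exact-coordinate duplicates
    dup <- c(rnd, rnd[1:100])
    wcd <- countWindowReads(win, dup, dup, dedup = TRUE)
    expect_equal(
        librarySizes(wcd)[["A"]],
        length(unique(paste(st, as.character(strand(rnd)))))
    )
})

test_that("rpm normalization is exact and linear", {
    expect_equal(rpmNormalize(20, 1e6), 20)
    expect_equal(rpmNormalize(0, 1e6), 0)
    expect_equal(rpmNormalize(287, 13950202), 287 * 1e6 / 13950202)
    counts <- c(3, 10, 0, 7)
    expect_equal(
        rpmNormalize(2 * counts, 5e5),
        2 * rpmNormalize(counts, 5e5)
    )
    expect_error(rpmNormalize(5, 0), "positive")
})

test_that("CGI coverage statistics reproduce their defining arithmetic", {
    ## published Table 1 cells as direct inputs
    s <- libraryStats(314334, 21763035, 19582, 28691)
    expect_equal(s$cgi_fraction_pct, 100 * 314334 / 21763035)
    expect_equal(round(s$per_cgi_depth), 16)
    s2 <- libraryStats(471279, 18821061, 19215, 28691)
    expect_equal(round(s2$cgi_fraction_pct, 1), 2.5)
    expect_equal(round(s2$per_cgi_depth, 1), 24.5)

    ## computed from reads: counts agree with overlap enumeration
    cgi <- GRanges("chr1", IRanges(c(1001L, 5001L), width = 500L))
    reads <- GRanges("chr1", IRanges(c(1100L, 1400L, 3000L), width = 36L))
    st <- cgiStats(reads, cgi)
    expect_equal(st$reads_in_cgi, 2)
    expect_equal(st$cgis_covered, 1)
    expect_equal(st$per_cgi_depth, 2)
    expect_false(st$degenerate)

    z <- cgiStats(reads[0], cgi)
    expect_true(z$degenerate)
    expect_equal(z$cgi_fraction_pct, 0)
    expect_equal(z$per_cgi_depth, 0)

    expect_error(cgiStats(reads, cgi[0]), "empty")
    expect_error(libraryStats(10, 5, 1), "exceed")
})
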