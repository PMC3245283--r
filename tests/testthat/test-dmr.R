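test_that("the window exact test matches enumeration and is symmetric", {
    expect_equal(fisherWindowTest(5, 5, 1e6, 1e6), 1)

    ## all 31 tables with these margins, enumerated by brute force
    expect_equal(
        fisherWindowTest(0, 30, 1e6, 1e6),
        bruteFisher(0, 30, 1e6, 1e6),
        tolerance = 1e-12
    )

    ## symmetry under swapping the two libraries
    set.seed(21)
    for (i in 1:20) {
        a <- sample(0:40, 1)
        b <- sample(0:40, 1)
        la <- sample(100:1e5, 1)
        lb <- sample(100:1e5, 1)
        expect_equal(
            fisherWindowTest(a, b, la, lb),
            fisherWindowTest(b, a, lb, la)
        )
    }

    ## agreement with the classical implementation on random tables
    set.seed(99)
    for (i in 1:25) {
        a <- sample(0:25, 1)
        b <- sample(0:25, 1)
        la <- sample(30:3000, 1)
        lb <- sample(30:3000, 1)
        ft <- stats::fisher.test(matrix(
            c(a, la - a, b, lb - b),
            nrow = 2, byrow = TRUE
        ))$p.value
        expect_equal(fisherWindowTest(a, b, la, lb), ft, tolerance = 1e-9)
    }

    expect_error(fisherWindowTest(-1, 3, 10, 10), "non-negative")
    expect_error(fisherWindowTest(3, 3, 0, 10), "positive")
    expect_error(fisherWindowTest(30, 3, 10, 10), "exceed")
})

.makeWC <- function(countA, countB, libA = 1e6, libB = 1e6,
                    width = 500L) {
    n <- length(countA)
    win <- GRanges("chr1", IRanges(seq(1L, by = 500L, length.out = n),
        width = width
    ))
    counts <- cbind(A = countA, B = countB)
    rpm <- cbind(A = countA * 1e6 / libA, B = countB * 1e6 / libB)
    se <- SummarizedExperiment(
        assays = list(counts = counts, rpm = rpm),
        rowRanges = win,
        colData = S4Vectors::DataFrame(
            librarySize = c(libA, libB), unplaced = c(0L, 0L),
            row.names = c("A", "B")
        ),
        metadata = list(windowSize = 500L)
    )
    new("WindowCounts", se)
}

test_that("the triple filter uses strict inequalities and Inf ratios pass", {
    ## rpm pairs (counts at library 1e6): 32.86/0 passes, 20/0 fails rpm,
    ## 400/19 passes via ratio 21.05
    wc <- .makeWC(c(33L, 20L, 400L, 39L), c(0L, 0L, 19L, 2L))
    dmrs <- callDmrs(wc)
    expect_equal(start(dmrs), c(1L, 1001L))
    expect_true(is.infinite(mcols(dmrs)$ratio[1]))
    expect_equal(mcols(dmrs)$ratio[2], 400 / 19)
    expect_true(all(mcols(dmrs)$direction == "A_hyper"))

    ## boundary semantics: rpm exactly 20 or ratio exactly 20 never pass
    wc2 <- .makeWC(c(20L, 400L), c(0L, 20L))
    expect_equal(length(callDmrs(wc2)), 0L)

    ## direction labels partition calls (no ties can pass the ratio filter)
    expect_true(all(mcols(dmrs)$direction %in% c("A_hyper", "B_hyper")))

    ## partial terminal windows are never called
    wc3 <- .makeWC(c(40L), c(0L), width = 300L)
    expect_equal(length(callDmrs(wc3)), 0L)
})

test_that("lowering any threshold never removes a called DMR", {
    set.seed(77)
    n <- 200L
    wc <- .makeWC(
        as.integer(rpois(n, 10) * sample(c(1, 30), n, TRUE)),
        as.integer(rpois(n, 10)),
        libA = 1e5, libB = 1e5
    )
    base <- DmrFilter()
    called <- start(callDmrs(wc, base))
    for (f in list(
        DmrFilter(rpmMin = 10), DmrFilter(ratioMin = 5),
        DmrFilter(pMax = 0.05)
    )) {
        expect_true(all(called %in% start(callDmrs(wc, f))))
    }
})

test_that("truth recovery handles vacuous and exact cases", {
    truth <- data.frame(
        chrom = "chr1", start = c(1L, 5001L), end = c(5000L, 10000L),
        meth_A = c(0.9, 0.4), meth_B = c(0.05, 0.4),
        is_dmr = c(TRUE, FALSE), direction = c("A_hyper", "none")
    )
    hit <- GRanges("chr1", IRanges(501L, 1000L))
    rec <- recoverTruth(hit, truth)
    expect_equal(rec$sensitivity, 1)
    expect_equal(rec$precision, 1)

    none <- recoverTruth(GRanges(), truth[!truth$is_dmr, ])
    expect_equal(none$sensitivity, 1)
    expect_equal(none$precision, 1)
    expect_true(none$vacuousSensitivity && none$vacuousPrecision)

    miss <- recoverTruth(GRanges("chr1", IRanges(6001L, 6500L)), truth)
    expect_equal(miss$sensitivity, 0)
    expect_equal(miss$precision, 0)
})
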