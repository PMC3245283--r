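test_that("term enrichment follows the hypergeometric model exactly", {
    bg <- paste0("g", 1:100)
    map <- data.frame(
        gene = c(paste0("g", 1:5), paste0("g", 6:20)),
        term = c(rep("T1", 5), rep("T2", 15))
    )
    ## k = K = n = 5: point mass 1 / C(100, 5)
    res <- enrichTerms(paste0("g", 1:5), map, bg)
    t1 <- res[res$term == "T1", ]
    expect_equal(t1$p_value, 1 / choose(100, 5), tolerance = 1e-12)
    expect_equal(t1$k, 5L)
    expect_true(t1$significant)

    ## saturated study: every term at p = 1
    sat <- enrichTerms(bg, map, bg)
    expect_true(all(sat$p_value == 1))

    ## terms without study hits are omitted
    expect_false("T2" %in% res$term)

    ## genes are matched case-insensitively with set semantics
    res2 <- enrichTerms(c("G1", "g1", "g2", "g3", "g4", "g5"), map, bg)
    expect_equal(res2[res2$term == "T1", "k"], 5L)

    expect_error(enrichTerms("g1", map, character(0)), "empty")
    expect_error(enrichTerms("absent", map, bg), "absent")

    ## conservation of expectation over a partitioned term map
    part <- data.frame(
        gene = bg,
        term = rep(c("A", "B", "C", "D"), each = 25)
    )
    all4 <- enrichTerms(paste0("g", seq(1, 100, by = 4)), part, bg,
        pThreshold = 1
    )
    expect_equal(sum(all4$n * all4$K / all4$N), 25)
})

test_that("the overlap test matches closed forms and brute enumeration", {
    ## disjoint lists
    expect_equal(
        overlapTest(paste0("a", 1:10), paste0("b", 1:10))$p_value, 1
    )

    ## identical lists of 10 from a population of 12,000
    ident <- overlapTest(paste0("g", 1:10), paste0("g", 1:10), 12000L)
    expect_equal(ident$overlap, 10L)
    expect_equal(ident$p_value, 1 / choose(12000, 10), tolerance = 1e-8)

    ## log-space tail equals exhaustive summation for populations <= 200
    set.seed(5)
    for (i in 1:50) {
        N <- sample(20:200, 1)
        K <- sample.int(N, 1)
        n <- sample.int(N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(
            MethCapDMR:::.hyperUpperTail(k, K, n, N),
            bruteHyperTail(k, K, n, N),
            tolerance = 1e-10
        )
    }

    ## growing the population makes a fixed observed overlap rarer
    a <- paste0("g", 1:50)
    b <- paste0("g", 26:75)
    p1 <- overlapTest(a, b, 1000L)$p_value
    p2 <- overlapTest(a, b, 2000L)$p_value
    expect_lt(p2, p1)

    expect_error(overlapTest(paste0("g", 1:30), "g1", 20L), "population")
})

test_that("permuted study sets give super-uniform enrichment p-values", {
    set.seed(31)
    bg <- paste0("g", 1:100)
    map <- data.frame(gene = paste0("g", 1:30), term = "T")
    p <- replicate(500, {
        r <- enrichTerms(sample(bg, 20), map, bg, pThreshold = 1)
        if (nrow(r)) r$p_value[1] else 1 # zero hits: P(X >= 0) = 1
    })
    ## anti-conservatism would push the empirical CDF above uniform
    ks <- suppressWarnings(
        stats::ks.test(p, "punif", alternative = "greater")
    )
    expect_gt(ks$p.value, 0.01)
})

test_that("platform intersection reproduces the published percentages", {
    hyper <- intersectWithPlatform(paste0("h", 1:1224), paste0("h", 1:221))
    expect_equal(round(hyper$percent, 1), 18.1)
    hypo <- intersectWithPlatform(paste0("h", 1:1216), paste0("h", 1:142))
    expect_equal(round(hypo$percent, 2), 11.68)

    none <- intersectWithPlatform(paste0("h", 1:10), character(0))
    expect_equal(none$n, 0L)
    expect_equal(none$percent, 0)
})
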