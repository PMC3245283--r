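suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

## small but fully featured simulation used across tests
tinyConfig <- function(...) {
    args <- list(
        seed = 7L, nChroms = 1L, chromLength = 60000L,
        nGenes = 2L, nCgis = 2L, nRepeats = 1L, nDmrs = 2L,
        readsPerLibrary = 3000L
    )
    do.call(SimConfig, utils::modifyList(args, list(...)))
}

## brute-force two-sided Fisher p via explicit binomial-coefficient
## enumeration (double-precision choose(), exact for margins <= 50)
bruteFisher <- function(a, b, libA, libB) {
    k <- a + b
    x <- max(0, k - libB):min(k, libA)
    probs <- choose(libA, x) * choose(libB, k - x) / choose(libA + libB, k)
    pObs <- choose(libA, a) * choose(libB, k - a) / choose(libA + libB, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

## brute-force upper-tail hypergeometric P(X >= k) by exhaustive summation
bruteHyperTail <- function(k, K, n, N) {
    if (k <= 0) {
        return(1)
    }
    x <- k:min(K, n)
    if (!length(x)) {
        return(0)
    }
    sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

## naive CpG o/e recount by character scanning (oracle for cpgOE)
naiveOE <- function(s) {
    ch <- strsplit(s, "")[[1]]
    nC <- sum(ch == "C")
    nG <- sum(ch == "G")
    L <- length(ch)
    di <- paste0(ch[-L], ch[-1])
    nCG <- sum(di == "CG")
    if (nC == 0 || nG == 0) {
        return(NA_real_)
    }
    nCG * L / (nC * nG)
}
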