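## Hypergeometric term enrichment and two-list overlap significance.
##
## Tail probabilities are computed in log space from log-binomial
## coefficients (lchoose + log-sum-exp), exact for the population sizes the
## analysis uses; no approximation enters.

## P(X >= k), X ~ Hypergeometric(N population, K successes, n draws)
.hyperUpperTail <- function(k, K, n, N) {
    if (k <= 0) {
        return(1)
    }
    hi <- min(K, n)
    if (k > hi) {
        return(0)
    }
    x <- k:hi
    lt <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
    m <- max(lt)
    min(1, exp(m) * sum(exp(lt - m)))
}

.normGenes <- function(x) unique(toupper(trimws(as.character(x))))

#' Hypergeometric term enrichment of a study gene set
#'
#' For every annotation term with at least one study hit, tests
#' over-representation of the term among the study genes against the
#' background: p = P(X >= k) for X hypergeometric with population N =
#' |background|, successes K = term genes in background, draws n = |study|.
#' Gene identifiers are matched case-insensitively and counted with set
#' semantics (a gene hit by several DMRs counts once). No multiple-testing
#' correction enters the significance call (raw p < \code{pThreshold});
#' a BH-adjusted column is emitted for information.
#'
#' @param studyGenes character vector of study gene identifiers (must be a
#'   subset of the background).
#' @param termMap data.frame with columns \code{gene}, \code{term} (see
#'   [readTermMap()]).
#' @param backgroundGenes character vector; the gene universe.
#' @param pThreshold raw significance cutoff (default 0.01).
#' @return A data.frame, one row per term with >= 1 study hit, ordered by
#'   p-value: term, k, K, n, N, p_value, fdr, significant, genes
#'   (space-joined study hits).
#' @export
enrichTerms <- function(studyGenes, termMap, backgroundGenes,
                        pThreshold = 0.01) {
    background <- .normGenes(backgroundGenes)
    if (length(background) == 0L) stop("background gene set is empty")
    study <- .normGenes(studyGenes)
    outside <- setdiff(study, background)
    if (length(outside)) {
        stop(
            "study genes absent from the background: ",
            paste(head(outside, 5L), collapse = ", ")
        )
    }
    stopifnot(all(c("gene", "term") %in% colnames(termMap)))
    mapGene <- toupper(trimws(termMap$gene))
    keep <- mapGene %in% background
    mapGene <- mapGene[keep]
    mapTerm <- as.character(termMap$term)[keep]
    byTerm <- split(mapGene, mapTerm)
    n <- length(study)
    N <- length(background)
    rows <- lapply(names(byTerm), function(tm) {
        termGenes <- unique(byTerm[[tm]])
        hitGenes <- intersect(termGenes, study)
        k <- length(hitGenes)
        if (k == 0L) {
            return(NULL)
        }
        K <- length(termGenes)
        data.frame(
            term = tm, k = k, K = K, n = n, N = N,
            p_value = .hyperUpperTail(k, K, n, N),
            genes = paste(sort(hitGenes), collapse = " "),
            stringsAsFactors = FALSE
        )
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) {
        return(data.frame(
            term = character(0), k = integer(0), K = integer(0),
            n = integer(0), N = integer(0), p_value = numeric(0),
            fdr = numeric(0), significant = logical(0), genes = character(0)
        ))
    }
    out <- do.call(rbind, rows)
    out$fdr <- p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_value < pThreshold
    out <- out[order(out$p_value, out$term), c(
        "term", "k", "K", "n", "N", "p_value", "fdr", "significant", "genes"
    )]
    rownames(out) <- NULL
    out
}

#' Hypergeometric significance of the overlap of two gene lists
#'
#' The probability of observing at least the seen overlap when \code{listA}
#' is drawn without replacement from a population of \code{populationN}
#' genes of which \code{listB} are "successes":
#' p = P(X >= |A intersect B|). The default population of 12,000 matches a
#' promoter-array universe. Identifiers are matched case-insensitively with
#' set semantics; the test is symmetric in the two lists.
#'
#' @param listA,listB character vectors of gene identifiers.
#' @param populationN population size (default 12000).
#' @return A list: overlap, nA, nB, population, p_value.
#' @examples
#' overlapTest(c("TP53", "BRCA1"), c("BRCA1", "MYC"), populationN = 100)
#' @export
overlapTest <- function(listA, listB, populationN = 12000L) {
    a <- .normGenes(listA)
    b <- .normGenes(listB)
    if (length(a) > populationN || length(b) > populationN) {
        stop("gene lists cannot exceed the population size")
    }
    k <- length(intersect(a, b))
    list(
        overlap = k, nA = length(a), nB = length(b),
        population = as.integer(populationN),
        p_value = .hyperUpperTail(k, length(b), length(a), populationN)
    )
}

#' Intersect DMR genes with an array platform
#'
#' Returns the subset of the gene list present on the platform
#' (case-insensitive) and its percentage of the input list.
#'
#' @param dmrGenes character vector of DMR-associated genes.
#' @param platformGenes character vector of genes on the platform.
#' @return A list: onPlatform (subset, original spelling), n, nInput,
#'   percent.
#' @examples
#' # 221 of 1224 published hypermethylated genes on the array: 18.1%
#' intersectWithPlatform(paste0("g", 1:1224), paste0("g", 1:221))$percent
#' @export
intersectWithPlatform <- function(dmrGenes, platformGenes) {
    input <- unique(trimws(as.character(dmrGenes)))
    plat <- .normGenes(platformGenes)
    on <- input[toupper(input) %in% plat]
    pct <- if (length(input)) 100 * length(on) / length(input) else 0
    list(
        onPlatform = on, n = length(on), nInput = length(input),
        percent = pct
    )
}
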