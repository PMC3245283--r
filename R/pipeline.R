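## End-to-end orchestration: simulate -> count -> call -> annotate ->
## (enrich/overlap), with a validated config, per-stage logging and a run
## manifest.

#' Validated pipeline configuration
#'
#' Aggregates every analysis parameter in one object: the window/filter
#' thresholds (defaults 500 bp, rpm > 20, ratio > 20, p < 0.001), the TSS
#' flank (5 kb), enrichment cutoff (0.01), overlap population (12,000),
#' deduplication flag, master seed, an optional simulation block and the
#' input file paths.
#'
#' @slot seed integer master seed.
#' @slot windowSize,flank,population integers.
#' @slot rpmMin,ratioMin,pMax,enrichP numeric thresholds.
#' @slot dedup logical; drop exact-coordinate duplicate reads.
#' @slot simulate list of [SimConfig()] overrides, or empty to analyse
#'   user-supplied inputs.
#' @slot inputs named list of file paths (genome, reads_a, reads_b, genes,
#'   cgi, repeats, truth, term_map, background, list_a, list_b).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(
        seed = "integer",
        windowSize = "integer",
        rpmMin = "numeric",
        ratioMin = "numeric",
        pMax = "numeric",
        flank = "integer",
        enrichP = "numeric",
        population = "integer",
        dedup = "logical",
        simulate = "list",
        inputs = "list"
    )
)

setValidity("PipelineConfig", function(object) {
    msg <- character()
    thr <- c(
        object@windowSize, object@rpmMin, object@ratioMin, object@pMax,
        object@flank, object@enrichP, object@population
    )
    if (any(is.na(thr)) || any(thr <= 0)) {
        msg <- c(msg, "all thresholds must be positive")
    }
    if (object@pMax > 1 || object@enrichP > 1) {
        msg <- c(msg, "p-value cutoffs must be probabilities")
    }
    missing <- vapply(object@inputs, function(p) {
        is.character(p) && !file.exists(p)
    }, logical(1))
    if (any(missing)) {
        msg <- c(msg, paste0(
            "input file(s) not found: ",
            paste(unlist(object@inputs[missing]), collapse = ", ")
        ))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PipelineConfig", function(object) {
    cat(sprintf(
        "PipelineConfig: seed %d; %d bp windows, rpm > %g, ratio > %g, p < %g\n",
        object@seed, object@windowSize, object@rpmMin, object@ratioMin,
        object@pMax
    ))
    cat(sprintf(
        "  flank %d bp; enrichment p < %g; overlap population %d; dedup %s\n",
        object@flank, object@enrichP, object@population, object@dedup
    ))
    cat(sprintf(
        "  mode: %s\n",
        if (length(object@simulate) || !length(object@inputs)) {
            "simulate inputs"
        } else {
            "user-supplied inputs"
        }
    ))
    invisible(NULL)
})

.simKeyMap <- c(
    seed = "seed", n_chroms = "nChroms", chrom_length = "chromLength",
    n_genes = "nGenes", n_cgis = "nCgis", n_repeats = "nRepeats",
    cgi_target_oe = "cgiTargetOE", background_oe = "backgroundOE",
    gc_background = "gcBackground", gc_cgi = "gcCgi", n_dmrs = "nDmrs",
    meth_high = "methHigh", meth_low = "methLow",
    meth_background = "methBackground", dmr_placement = "dmrPlacement",
    region_length = "regionLength", reads_per_library = "readsPerLibrary",
    fragment_length = "fragmentLength", read_length = "readLength",
    cgi_length = "cgiLength", repeat_length = "repeatLength",
    gene_length = "geneLength", sampling_floor = "samplingFloor"
)

.inputKeys <- c(
    "genome", "reads_a", "reads_b", "genes", "cgi", "repeats", "truth",
    "term_map", "background", "list_a", "list_b"
)

.checkScalar <- function(x, key, type = c("numeric", "logical")) {
    type <- match.arg(type)
    ok <- length(x) == 1L && !is.na(x) &&
        if (type == "numeric") is.numeric(x) else is.logical(x)
    if (!ok) {
        stop(
            "config key '", key, "' must be a single ", type, " value",
            call. = FALSE
        )
    }
    x
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent named list), rejects unknown
#' keys (catching typos), checks types, applies the default thresholds
#' (500/20/20/0.001, flank 5000, enrichment p 0.01, population 12000) and
#' verifies that referenced input files exist. An empty config runs the
#' bundled simulation demo with all defaults.
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated [PipelineConfig-class] object.
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("no such config file: ", config)
        config <- yaml::read_yaml(config) %||% list()
    }
    stopifnot(is.list(config))
    known <- c(
        "seed", "window_size", "rpm_min", "ratio_min", "p_max", "flank",
        "enrich_p", "population", "dedup", "simulate", "inputs"
    )
    unknown <- setdiff(names(config), known)
    if (length(unknown)) {
        stop(
            "unknown config key(s): ", paste(unknown, collapse = ", "),
            "; known keys: ", paste(known, collapse = ", "),
            call. = FALSE
        )
    }
    num <- function(key, default) {
        .checkScalar(config[[key]] %||% default, key, "numeric")
    }
    sim <- config$simulate %||% list()
    if (!is.list(sim)) stop("'simulate' must be a mapping", call. = FALSE)
    unknownSim <- setdiff(names(sim), names(.simKeyMap))
    if (length(unknownSim)) {
        stop(
            "unknown simulate key(s): ", paste(unknownSim, collapse = ", "),
            call. = FALSE
        )
    }
    inputs <- config$inputs %||% list()
    if (!is.list(inputs)) stop("'inputs' must be a mapping", call. = FALSE)
    unknownIn <- setdiff(names(inputs), .inputKeys)
    if (length(unknownIn)) {
        stop(
            "unknown inputs key(s): ", paste(unknownIn, collapse = ", "),
            call. = FALSE
        )
    }
    obj <- new("PipelineConfig",
        seed = as.integer(num("seed", 1L)),
        windowSize = as.integer(num("window_size", 500L)),
        rpmMin = num("rpm_min", 20),
        ratioMin = num("ratio_min", 20),
        pMax = num("p_max", 0.001),
        flank = as.integer(num("flank", 5000L)),
        enrichP = num("enrich_p", 0.01),
        population = as.integer(num("population", 12000L)),
        dedup = .checkScalar(config$dedup %||% FALSE, "dedup", "logical"),
        simulate = sim,
        inputs = inputs
    )
    validObject(obj)
    obj
}

.pipelineStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        stop(
            "pipeline stage '", name, "' failed: ", conditionMessage(e),
            call. = FALSE
        )
    })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (unless user inputs are
#' supplied), count, call, annotate, and optionally recover (when ground
#' truth is available), enrich and overlap — writing each stage's table
#' into \code{outdir} together with a manifest recording the seed, input
#' checksums and per-stage row counts. Re-running with an identical
#' configuration reproduces identical output bytes.
#'
#' @param config a [PipelineConfig-class], a YAML path or a named list (run
#'   through [validateConfig()]).
#' @param outdir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with the called DMRs, the annotation, the
#'   recovery/enrichment/overlap results where applicable, and the manifest
#'   data.frame.
#' @export
runPipeline <- function(config = list(), outdir, quiet = FALSE) {
    if (!is(config, "PipelineConfig")) config <- validateConfig(config)
    validObject(config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (!quiet) message("[MethCapDMR] ", ...)
    manifest <- list()
    note <- function(stage, file, rows) {
        manifest[[length(manifest) + 1L]] <<- data.frame(
            stage = stage, file = basename(file), rows = rows,
            md5 = unname(md5sum(file)), stringsAsFactors = FALSE
        )
    }
    inputs <- config@inputs
    out <- function(f) file.path(outdir, f)
    results <- list()

    doSim <- length(config@simulate) > 0L || is.null(inputs$genome)
    if (doSim) {
        .pipelineStage("simulate", {
            simArgs <- config@simulate
            names(simArgs) <- .simKeyMap[names(simArgs)]
            if (is.null(simArgs$seed)) simArgs$seed <- config@seed
            simCfg <- do.call(SimConfig, simArgs)
            sim <- simulateGenome(simCfg)
            meth <- simulateMethylomes(sim, simCfg)
            readsA <- simulateCaptureReads(sim, meth$methA, simCfg,
                seed = simCfg@seed + 2L
            )
            readsB <- simulateCaptureReads(sim, meth$methB, simCfg,
                seed = simCfg@seed + 3L
            )
            writeFastaGenome(sim@genome, out("genome.fa"))
            writeGeneTable(sim@genes, sim@exons, out("genes.tsv"))
            writeBed(sim@cgi, out("cgi.bed"))
            writeBed(sim@repeats, out("repeats.bed"))
            writeTruthTable(meth$truth, out("truth.tsv"))
            writeBed(readsA, out("reads_A.bed"))
            writeBed(readsB, out("reads_B.bed"))
            inputs <- list(
                genome = out("genome.fa"), genes = out("genes.tsv"),
                cgi = out("cgi.bed"), repeats = out("repeats.bed"),
                truth = out("truth.tsv"), reads_a = out("reads_A.bed"),
                reads_b = out("reads_B.bed"),
                term_map = inputs$term_map,
                background = inputs$background,
                list_a = inputs$list_a, list_b = inputs$list_b
            )
            note("simulate", out("genome.fa"), length(sim@genome))
            note("simulate", out("reads_A.bed"), length(readsA))
            note("simulate", out("reads_B.bed"), length(readsB))
            note("simulate", out("truth.tsv"), nrow(meth$truth))
            say(
                "simulate: ", length(sim@genome), " chromosome(s), ",
                length(readsA), "+", length(readsB), " reads, ",
                sum(meth$truth$is_dmr), " planted DMRs"
            )
        })
    }

    wc <- .pipelineStage("count", {
        for (key in c("genome", "reads_a", "reads_b", "genes")) {
            if (is.null(inputs[[key]])) {
                stop("required input '", key, "' missing")
            }
        }
        genome <- readFastaGenome(inputs$genome)
        readsA <- readBed(inputs$reads_a, genome)
        readsB <- readBed(inputs$reads_b, genome)
        windows <- tileGenomeWindows(genome, config@windowSize)
        wc <- countWindowReads(windows, readsA, readsB,
            dedup = config@dedup
        )
        writeWindowCounts(wc, out("counts.tsv"))
        note("count", out("counts.tsv"), length(windows))
        say(
            "count: ", length(windows), " windows, libraries ",
            paste(librarySizes(wc), collapse = "/"),
            ", unplaced ", paste(unplacedReads(wc), collapse = "/")
        )
        wc
    })

    dmrs <- .pipelineStage("call", {
        filter <- DmrFilter(
            config@windowSize, config@rpmMin, config@ratioMin, config@pMax
        )
        dmrs <- callDmrs(testWindows(wc), filter)
        writeDmrTable(dmrs, out("dmrs.tsv"))
        note("call", out("dmrs.tsv"), length(dmrs))
        say(
            "call: ", length(dmrs), " DMRs (",
            sum(mcols(dmrs)$direction == "A_hyper"), " A_hyper, ",
            sum(mcols(dmrs)$direction == "B_hyper"), " B_hyper)"
        )
        dmrs
    })
    results$dmrs <- dmrs

    annotated <- .pipelineStage("annotate", {
        gm <- readGeneTable(inputs$genes)
        repeats <- if (!is.null(inputs$repeats)) {
            readBed(inputs$repeats)
        } else {
            GRanges()
        }
        genome <- readFastaGenome(inputs$genome)
        annotated <- annotateDmrs(dmrs, gm$genes, gm$exons, repeats, genome,
            flank = config@flank
        )
        writeDmrTable(annotated, out("annotated.tsv"))
        note("annotate", out("annotated.tsv"), length(annotated))
        cat1 <- stratifyOE(
            annotated, genome,
            mcols(annotated)$category
        )$summary
        write.table(cat1, out("oe_summary.tsv"),
            sep = "\t", quote = FALSE,
            row.names = FALSE
        )
        note("annotate", out("oe_summary.tsv"), nrow(cat1))
        say("annotate: ", length(annotated), " DMRs annotated")
        annotated
    })
    results$annotated <- annotated

    if (!is.null(inputs$truth)) {
        results$recovery <- .pipelineStage("recover", {
            truth <- readTruthTable(inputs$truth)
            rec <- recoverTruth(dmrs, truth)
            df <- data.frame(
                sensitivity = rec$sensitivity, precision = rec$precision,
                n_planted = rec$nPlanted, n_called = rec$nCalled
            )
            write.table(df, out("recovery.tsv"),
                sep = "\t", quote = FALSE,
                row.names = FALSE
            )
            note("recover", out("recovery.tsv"), 1L)
            say(sprintf(
                "recover: sensitivity %.3f, precision %.3f",
                rec$sensitivity, rec$precision
            ))
            rec
        })
    }

    if (!is.null(inputs$term_map)) {
        results$enrichment <- .pipelineStage("enrich", {
            gm <- readGeneTable(inputs$genes)
            assoc <- associateGenes(dmrs, gm$genes, flank = config@flank)
            study <- unique(assoc$gene_id)
            background <- if (!is.null(inputs$background)) {
                readGeneList(inputs$background)
            } else {
                mcols(gm$genes)$gene_id
            }
            termMap <- readTermMap(inputs$term_map)
            enr <- enrichTerms(study, termMap, background,
                pThreshold = config@enrichP
            )
            write.table(enr, out("enrichment.tsv"),
                sep = "\t",
                quote = FALSE, row.names = FALSE
            )
            note("enrich", out("enrichment.tsv"), nrow(enr))
            say(
                "enrich: ", nrow(enr), " terms tested, ",
                sum(enr$significant), " significant"
            )
            enr
        })
    }

    if (!is.null(inputs$list_a) && !is.null(inputs$list_b)) {
        results$overlap <- .pipelineStage("overlap", {
            ov <- overlapTest(
                readGeneList(inputs$list_a), readGeneList(inputs$list_b),
                populationN = config@population
            )
            df <- data.frame(
                overlap = ov$overlap, n_a = ov$nA, n_b = ov$nB,
                population = ov$population, p_value = ov$p_value
            )
            write.table(df, out("overlap.tsv"),
                sep = "\t", quote = FALSE,
                row.names = FALSE
            )
            note("overlap", out("overlap.tsv"), 1L)
            say(sprintf(
                "overlap: %d common genes, p = %.3g", ov$overlap,
                ov$p_value
            ))
            ov
        })
    }

    manifestDf <- do.call(rbind, manifest)
    header <- c(
        sprintf(
            "# MethCapDMR %s run manifest; seed %d",
            as.character(packageVersion("MethCapDMR")), config@seed
        ),
        sprintf(
            "# filter: window %d bp, rpm > %g, ratio > %g, p < %g; flank %d",
            config@windowSize, config@rpmMin, config@ratioMin, config@pMax,
            config@flank
        )
    )
    con <- file(out("manifest.tsv"), "w")
    writeLines(header, con)
    suppressWarnings(write.table(manifestDf, con,
        sep = "\t", quote = FALSE,
        row.names = FALSE
    ))
    close(con)
    results$manifest <- manifestDf
    say("done: ", outdir)
    invisible(results)
}

#' Write/read the per-window count table
#'
#' Tab-separated columns chrom, start, end (1-based inclusive), count_A,
#' count_B, rpm_A, rpm_B; the commented header records the window size,
#' library sizes and unplaced-read counts so the object can be
#' reconstructed exactly (rpm is recomputed from counts on read).
#'
#' @param wc a [WindowCounts-class] object.
#' @param path file path.
#' @return \code{readWindowCounts}: a [WindowCounts-class] object.
#' @export
writeWindowCounts <- function(wc, path) {
    stopifnot(is(wc, "WindowCounts"))
    counts <- assay(wc, "counts")
    rpm <- assay(wc, "rpm")
    gr <- rowRanges(wc)
    libs <- librarySizes(wc)
    unpl <- unplacedReads(wc)
    df <- data.frame(
        chrom = as.character(seqnames(gr)),
        start = start(gr), end = end(gr),
        count_A = counts[, "A"], count_B = counts[, "B"],
        rpm_A = sprintf("%.4f", rpm[, "A"]),
        rpm_B = sprintf("%.4f", rpm[, "B"])
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        .openHeader("window counts"),
        sprintf(
            "# window_size=%d library_size_A=%d library_size_B=%d unplaced_A=%d unplaced_B=%d",
            S4Vectors::metadata(wc)$windowSize, libs[["A"]], libs[["B"]],
            unpl[["A"]], unpl[["B"]]
        )
    ), con)
    suppressWarnings(write.table(df, con,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
    ))
    invisible(path)
}

#' @rdname writeWindowCounts
#' @export
readWindowCounts <- function(path) {
    lines <- readLines(path, n = 10L)
    meta <- grep("^# window_size=", lines, value = TRUE)
    if (!length(meta)) stop("not a window-count table: ", path)
    kv <- strsplit(strsplit(sub("^# ", "", meta[1]), " ")[[1]], "=")
    vals <- setNames(
        as.integer(vapply(kv, `[`, character(1), 2L)),
        vapply(kv, `[`, character(1), 1L)
    )
    df <- read.table(path,
        header = TRUE, sep = "\t", comment.char = "#",
        stringsAsFactors = FALSE
    )
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    counts <- cbind(A = df$count_A, B = df$count_B)
    libs <- c(vals[["library_size_A"]], vals[["library_size_B"]])
    rpm <- sweep(counts, 2L, libs, function(x, n) x * 1e6 / n)
    se <- SummarizedExperiment(
        assays = list(counts = counts, rpm = rpm),
        rowRanges = gr,
        colData = S4Vectors::DataFrame(
            librarySize = libs,
            unplaced = c(vals[["unplaced_A"]], vals[["unplaced_B"]]),
            row.names = c("A", "B")
        ),
        metadata = list(windowSize = vals[["window_size"]])
    )
    new("WindowCounts", se)
}
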