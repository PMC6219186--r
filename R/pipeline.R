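## end-to-end orchestration: simulate -> call peaks -> annotate ->
## TSS statistics -> expression integration, with stage outputs on disk,
## idempotent re-runs and a summary report.

#' Pipeline run configuration
#'
#' Collects everything one pipeline run needs. With `inputs = NULL` the
#' run starts from the synthetic-data generator; otherwise `inputs` names
#' existing files: `genome` (FASTA), `genes` (BED6/GFF3), `fg` and `bg`
#' (qBED insertion tables) and `expression` (TSV).
#'
#' @param outdir output directory (created if needed).
#' @param sim a [simParams()] list (simulated runs).
#' @param peaks a [peakCallParams()] list.
#' @param hopThreshold,pThreshold,foldThreshold integration thresholds.
#' @param seed integer seed driving every random stage.
#' @param overwrite recompute stages even when their outputs are fresh.
#' @param inputs optional named list of input paths (see above).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(outdir, sim = simParams(),
                      peaks = peakCallParams(), hopThreshold = 5,
                      pThreshold = 0.01, foldThreshold = 2, seed = 1L,
                      overwrite = FALSE, inputs = NULL) {
    if (!is.null(inputs)) {
        need <- c("genome", "genes", "fg", "bg", "expression")
        missing <- setdiff(need, names(inputs))
        if (length(missing))
            stop(sprintf("inputs must name file(s): --%s",
                         paste(missing, collapse = ", --")))
        for (nm in need)
            if (!file.exists(inputs[[nm]]))
                stop(sprintf("input file for --%s not found: %s", nm,
                             inputs[[nm]]))
    }
    structure(list(outdir = outdir, sim = sim, peaks = peaks,
                   hopThreshold = hopThreshold, pThreshold = pThreshold,
                   foldThreshold = foldThreshold, seed = as.integer(seed),
                   overwrite = isTRUE(overwrite), inputs = inputs),
              class = "RunConfig")
}

.fresh <- function(outputs, inputs = character()) {
    if (!all(file.exists(outputs))) return(FALSE)
    if (!length(inputs)) return(TRUE)
    min(file.mtime(outputs)) >= max(file.mtime(inputs))
}

.stage <- function(name, outdir, expr) {
    marker <- file.path(outdir, paste0(name, ".partial"))
    file.create(marker)
    res <- tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
    unlink(marker)
    res
}

#' Read simulation truth written by [writeTruth()]
#'
#' @param path JSON file.
#' @return a `SimTruth` list.
#' @export
readTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    loci <- GRanges(x$loci$chrom,
                    IRanges(x$loci$start + 1L, x$loci$end))
    mcols(loci)$gene_id <- x$loci$gene_id
    structure(list(loci = loci, boundGenes = x$loci$gene_id,
                   geneTable = x$genes, placement = x$placement),
              class = "SimTruth")
}

#' Run the full calling-card analysis pipeline
#'
#' Executes, in order: input generation or loading, hop deduplication,
#' peak calling, nearest-gene/TSS annotation, TSS-distance statistics
#' against a random-position control (and against the raw background
#' insertions), and expression integration. Stage outputs are written
#' under `config$outdir`; a stage whose outputs already exist and are
#' newer than its inputs is skipped unless `overwrite`, so immediate
#' re-runs are idempotent. A failed stage aborts with its name and leaves
#' a `<stage>.partial` marker in the output directory.
#'
#' @param config a [runConfig()] list.
#' @return a `ccReport` list with hop totals, peak counts, TSS test
#'   results, the association table with Fisher p, responsive fraction,
#'   strong-target counts, truth recovery (simulated runs) and all file
#'   paths; printed compactly by its print method.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    out <- config$outdir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(out, f)
    simulated <- is.null(config$inputs)
    truth <- NULL

    if (simulated) {
        simFiles <- pth(c("genome.fa", "genes.bed", "fg.qbed", "bg.qbed",
                          "expression.tsv", "truth.json"))
        if (config$overwrite || !.fresh(simFiles)) {
            sim <- .stage("simulate", out, {
                sim <- simulateCallingCards(config$sim, config$seed)
                writeXStringSet(sim$genome, pth("genome.fa"))
                g <- data.frame(
                    chrom = as.character(seqnames(sim$genes)),
                    start = start(sim$genes) - 1L, end = end(sim$genes),
                    name = mcols(sim$genes)$gene_id, score = 0L,
                    strand = as.character(strand(sim$genes)))
                write.table(g, pth("genes.bed"), sep = "\t",
                            quote = FALSE, row.names = FALSE,
                            col.names = FALSE)
                writeQbed(sim$fg, pth("fg.qbed"))
                writeQbed(sim$bg, pth("bg.qbed"))
                writeExpressionTable(sim$expression,
                                     pth("expression.tsv"))
                writeTruth(sim$truth, pth("truth.json"))
                sim
            })
            ttaa <- sim$ttaa; genes <- sim$genes
            fg <- sim$fg; bg <- sim$bg
            expr <- sim$expression; truth <- sim$truth
        } else {
            message("stage 'simulate': outputs fresh, skipped")
            ttaa <- ttaaIndex(pth("genome.fa"))
            genes <- readGeneModels(pth("genes.bed"))
            fg <- dedupHops(readQbed(pth("fg.qbed"), "FG"))
            bg <- dedupHops(readQbed(pth("bg.qbed"), "BG"))
            expr <- readExpressionTable(pth("expression.tsv"))
            truth <- readTruth(pth("truth.json"))
        }
    } else {
        loaded <- .stage("load", out, {
            ttaa <- ttaaIndex(config$inputs$genome)
            list(ttaa = ttaa,
                 genes = readGeneModels(config$inputs$genes),
                 fg = dedupHops(readQbed(config$inputs$fg, "FG", ttaa)),
                 bg = dedupHops(readQbed(config$inputs$bg, "BG", ttaa)),
                 expr = readExpressionTable(config$inputs$expression))
        })
        ttaa <- loaded$ttaa; genes <- loaded$genes
        fg <- loaded$fg; bg <- loaded$bg; expr <- loaded$expr
    }

    peaks <- .stage("callpeaks", out, {
        p <- callPeaks(fg, bg, ttaa, config$peaks)
        p <- annotatePeaks(p, genes)
        writePeaks(p, pth("peaks.tsv"))
        p
    })
    sig <- peaks[mcols(peaks)$significant]

    tssStats <- .stage("tssdist", out, {
        if (length(sig)) {
            rnd <- randomPositions(seqlengths(ttaa), length(sig),
                                   config$seed)
            dPeaks <- mcols(sig)$tssDistance
            dRandom <- tssDistances(rnd, genes)
            dBackground <- tssDistances(bg, genes)
            hist <- tssDistanceHistogram(dPeaks)
            write.table(hist, pth("tss_hist.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            list(vsRandom = mannWhitneyU(dPeaks, dRandom),
                 vsRandomLess = mannWhitneyU(dPeaks, dRandom, "less"),
                 vsBackground = mannWhitneyU(dPeaks, dBackground),
                 medianPeak = stats::median(dPeaks),
                 medianRandom = stats::median(dRandom),
                 controlSeed = config$seed)
        } else NULL
    })

    integ <- .stage("integrate", out, {
        ## per-gene burden counts candidate clusters; singleton clusters
        ## are unclustered background and do not contribute. Sparse
        ## candidates populate the "<= threshold insertions" stratum.
        hp <- hopsPerGene(peaks[mcols(peaks)$candidate],
                          mcols(genes)$gene_id)
        rec <- buildGeneTargetTable(hp, expr, config$hopThreshold,
                                    config$pThreshold,
                                    config$foldThreshold)
        assoc <- tryCatch(
            associationTest(rec, config$hopThreshold, config$pThreshold),
            error = function(e) NULL)
        strong <- selectStrongTargets(rec, config$hopThreshold,
                                      config$pThreshold,
                                      config$foldThreshold)
        ## the headline responsive fraction is computed among *targeted*
        ## genes: genes adjacent to a significant peak, with more than
        ## hopThreshold insertions
        sigGenes <- unique(stats::na.omit(mcols(sig)$nearestGene))
        tsel <- rec$gene_id %in% sigGenes &
            rec$totalHops > config$hopThreshold & !is.na(rec$pAdj)
        respTargets <- if (any(tsel))
            mean(rec$pAdj[tsel] <= config$pThreshold) else NA_real_
        writeTargetTable(rec, pth("targets.tsv"))
        list(records = rec, association = assoc, strong = strong,
             responsiveFractionTargets = respTargets,
             nTargetGenes = sum(tsel))
    })

    recovery <- if (!is.null(truth))
        evaluateRecovery(peaks, truth) else NULL

    report <- structure(list(
        seed = config$seed, outdir = out, simulated = simulated,
        hops = c(fg = length(fg), bg = length(bg)),
        nClusters = length(peaks),
        nCandidates = sum(mcols(peaks)$candidate),
        nSignificant = length(sig),
        hopHistogram = hopCountHistogram(
            peaks[mcols(peaks)$candidate]),
        tss = tssStats, association = integ$association,
        responsiveFractionTargets = integ$responsiveFractionTargets,
        nTargetGenes = integ$nTargetGenes,
        strongUp = integ$strong$up, strongDown = integ$strong$down,
        recovery = recovery,
        peaks = peaks, records = integ$records,
        files = list(peaks = pth("peaks.tsv"),
                     targets = pth("targets.tsv"))),
        class = "ccReport")
    .writeReport(report, pth("report.json"))
    report
}

.writeReport <- function(report, path) {
    x <- list(seed = report$seed, simulated = report$simulated,
              fgHops = unname(report$hops["fg"]),
              bgHops = unname(report$hops["bg"]),
              nClusters = report$nClusters,
              nCandidates = report$nCandidates,
              nSignificant = report$nSignificant)
    if (!is.null(report$tss)) {
        x$tssMannWhitneyPvsRandom <- report$tss$vsRandom$pValue
        x$tssMannWhitneyPvsRandomOneSided <- report$tss$vsRandomLess$pValue
        x$tssMannWhitneyPvsBackground <- report$tss$vsBackground$pValue
        x$tssMedianPeak <- report$tss$medianPeak
        x$tssMedianRandom <- report$tss$medianRandom
    }
    if (!is.null(report$association)) {
        x$associationTable <- unclass(report$association$table)
        x$fisherP <- report$association$pValue
        x$responsiveFractionHigh <-
            report$association$responsiveFractionHigh
        x$responsiveFractionLow <-
            report$association$responsiveFractionLow
    }
    x$responsiveFractionTargets <- report$responsiveFractionTargets
    x$nTargetGenes <- report$nTargetGenes
    x$nStrongUp <- length(report$strongUp)
    x$nStrongDown <- length(report$strongDown)
    if (!is.null(report$recovery))
        x$recovery <- report$recovery
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @export
print.ccReport <- function(x, ...) {
    cat(sprintf("calling-card pipeline report (seed %d)\n", x$seed))
    cat(sprintf("  hops: %d foreground / %d background\n",
                x$hops["fg"], x$hops["bg"]))
    cat(sprintf("  clusters: %d; candidates: %d; significant peaks: %d\n",
                x$nClusters, x$nCandidates, x$nSignificant))
    if (!is.null(x$tss))
        cat(sprintf(
            "  TSS distance, peaks vs random: U = %g, p = %.3g (median %g vs %g bp)\n",
            x$tss$vsRandom$U, x$tss$vsRandom$pValue, x$tss$medianPeak,
            x$tss$medianRandom))
    if (!is.null(x$association)) {
        cat(sprintf(
            "  association (hops > threshold x responsive): Fisher p = %.3g\n",
            x$association$pValue))
        cat(sprintf(
            "  responsive fraction: %.3f among high-hop, %.3f among low-hop genes\n",
            x$association$responsiveFractionHigh,
            x$association$responsiveFractionLow))
    }
    if (!is.null(x$responsiveFractionTargets) &&
        !is.na(x$responsiveFractionTargets))
        cat(sprintf(
            "  responsive fraction among targeted genes (> threshold hops): %.3f (n = %d)\n",
            x$responsiveFractionTargets, x$nTargetGenes))
    cat(sprintf("  strong targets: %d up, %d down\n",
                length(x$strongUp), length(x$strongDown)))
    if (!is.null(x$recovery))
        cat(sprintf(
            "  truth recovery: recall %.3f, precision %.3f, gene accuracy %.3f\n",
            x$recovery$recall, x$recovery$precision,
            x$recovery$geneAccuracy))
    invisible(x)
}

#' Combine two constructs (fusion orientations) of one experiment
#'
#' Computes the peak-level and gene-level overlap between two completed
#' runs on the same genome, and re-runs the expression integration on the
#' union of their target genes, with per-gene hops summed across
#' constructs — the two fusion orientations sample the same binding
#' landscape and their target lists are pooled downstream.
#'
#' @param reportA,reportB two [runPipeline()] results on the same genome.
#' @return list with `peakVenn`, `geneVenn`, `union` (association and
#'   strong targets on the pooled records) and the per-construct reports.
#' @export
twoConstructAnalysis <- function(reportA, reportB) {
    stopifnot(inherits(reportA, "ccReport"), inherits(reportB, "ccReport"))
    slA <- seqlengths(reportA$peaks); slB <- seqlengths(reportB$peaks)
    common <- intersect(names(slA), names(slB))
    if (!length(common) || !identical(slA[common], slB[common]))
        stop("the two runs are not on the same genome")
    sigA <- reportA$peaks[mcols(reportA$peaks)$significant]
    sigB <- reportB$peaks[mcols(reportB$peaks)$significant]
    peakVenn <- intervalOverlapVenn(sigA, sigB)
    targA <- unique(stats::na.omit(mcols(sigA)$nearestGene))
    targB <- unique(stats::na.omit(mcols(sigB)$nearestGene))
    geneVenn <- geneSetVenn(targA, targB)
    recA <- reportA$records; recB <- reportB$records
    m <- match(recA$gene_id, recB$gene_id)
    pooled <- recA
    pooled$totalHops <- recA$totalHops +
        ifelse(is.na(m), 0L, recB$totalHops[m])
    pooled$nPeaks <- recA$nPeaks + ifelse(is.na(m), 0L, recB$nPeaks[m])
    pooled$isTarget <- pooled$totalHops > 5
    assoc <- tryCatch(associationTest(pooled), error = function(e) NULL)
    strong <- selectStrongTargets(pooled)
    list(peakVenn = peakVenn, geneVenn = geneVenn,
         union = list(records = pooled, association = assoc,
                      strong = strong),
         constructA = reportA, constructB = reportB)
}
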