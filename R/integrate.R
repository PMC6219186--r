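## insertion-expression integration: per-gene hop burden joined with a
## differential-expression table, Fisher association, target selection.

#' Read a gene-level differential-expression table
#'
#' Tab-delimited with a header; column names configurable. `logFC` is the
#' log2 fold change of knockdown versus control and `adj_p` the
#' FDR-adjusted p-value.
#'
#' @param path TSV file.
#' @param geneCol,lfcCol,pCol column names for gene id, log2 fold change
#'   and adjusted p.
#' @return `data.frame(gene_id, logFC, pAdj)`, one row per gene.
#' @export
readExpressionTable <- function(path, geneCol = "gene_id",
                                lfcCol = "logFC", pCol = "adj_p") {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(c(geneCol, lfcCol, pCol), colnames(tab))
    if (length(missing))
        stop(sprintf("expression table lacks column(s): %s",
                     paste(missing, collapse = ", ")))
    out <- data.frame(gene_id = as.character(tab[[geneCol]]),
                      logFC = as.numeric(tab[[lfcCol]]),
                      pAdj = as.numeric(tab[[pCol]]))
    if (anyDuplicated(out$gene_id))
        stop("expression table has duplicated gene ids")
    if (any(out$pAdj < 0 | out$pAdj > 1, na.rm = TRUE))
        stop("adjusted p-values must lie in [0, 1]")
    out
}

#' Write a gene-level expression table readable by [readExpressionTable()]
#'
#' @param expr `data.frame(gene_id, logFC, pAdj)`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(expr, path) {
    tab <- data.frame(gene_id = expr$gene_id, logFC = expr$logFC,
                      adj_p = expr$pAdj)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Total hops and peak count per gene
#'
#' Sums the observed hops of annotated peaks over their nearest gene. The
#' per-gene hop total is the insertion burden used for target selection
#' ("more than 5 insertions"). Genes in `geneIds` without any peak are
#' reported with zero hops.
#'
#' @param peaks an annotated [CalledPeaks-class] (see [annotatePeaks()]),
#'   or a data.frame with columns `nearestGene` and `hops`.
#' @param geneIds optional character vector of all gene ids to report.
#' @return `data.frame(gene_id, totalHops, nPeaks)`.
#' @export
hopsPerGene <- function(peaks, geneIds = NULL) {
    if (is(peaks, "CalledPeaks")) {
        if (is.null(mcols(peaks)$nearestGene))
            stop("peaks are not annotated; run annotatePeaks() first")
        tab <- data.frame(nearestGene = mcols(peaks)$nearestGene,
                          hops = mcols(peaks)$hops)
    } else if (is.data.frame(peaks) &&
               all(c("nearestGene", "hops") %in% colnames(peaks))) {
        tab <- peaks
    } else {
        stop("'peaks' must be an annotated CalledPeaks or a data.frame ",
             "with columns nearestGene and hops")
    }
    tab <- tab[!is.na(tab$nearestGene), , drop = FALSE]
    agg <- if (nrow(tab))
        data.frame(gene_id = names(split(tab$hops, tab$nearestGene)),
                   totalHops = vapply(split(tab$hops, tab$nearestGene),
                                      sum, numeric(1)),
                   nPeaks = vapply(split(tab$hops, tab$nearestGene),
                                   length, integer(1)))
    else data.frame(gene_id = character(), totalHops = numeric(),
                    nPeaks = integer())
    rownames(agg) <- NULL
    if (!is.null(geneIds)) {
        geneIds <- as.character(geneIds)
        extra <- setdiff(geneIds, agg$gene_id)
        agg <- rbind(agg, data.frame(gene_id = extra, totalHops = 0,
                                     nPeaks = 0L))
        agg <- agg[match(union(geneIds, agg$gene_id), agg$gene_id), ,
                   drop = FALSE]
        rownames(agg) <- NULL
    }
    agg$totalHops <- as.integer(agg$totalHops)
    agg
}

#' Join per-gene hop counts with expression responses
#'
#' Exact string join on gene id (optionally case-folded). Genes missing
#' from the expression table are kept with NA expression and their count
#' is reported in a message — never silently dropped. Adds the selection
#' flags used downstream: `isTarget` (totalHops > hopThreshold),
#' `isResponsive` (pAdj <= pThreshold) and `isStrong` (responsive with
#' linear fold change above `foldThreshold`, i.e. |logFC| >
#' log2(foldThreshold)).
#'
#' @param hops output of [hopsPerGene()].
#' @param expr output of [readExpressionTable()].
#' @param hopThreshold per-gene hop total above which a gene is a target
#'   (default 5: "more than 5 insertions").
#' @param pThreshold adjusted-p cutoff for a responsive gene (default
#'   0.01, inclusive).
#' @param foldThreshold linear fold-change cutoff for a strong target
#'   (default 2).
#' @param caseFold case-fold gene ids before joining.
#' @return `data.frame` of gene target records.
#' @export
buildGeneTargetTable <- function(hops, expr, hopThreshold = 5,
                                 pThreshold = 0.01, foldThreshold = 2,
                                 caseFold = FALSE) {
    h <- hops; e <- expr
    if (caseFold) {
        h$gene_id <- toupper(h$gene_id)
        e$gene_id <- toupper(e$gene_id)
    }
    if (anyDuplicated(e$gene_id))
        stop("expression table has duplicated gene ids")
    i <- match(h$gene_id, e$gene_id)
    unmatched <- sum(is.na(i) & h$totalHops > 0)
    if (unmatched)
        message(sprintf(
            "%d gene(s) with hops lack expression data (kept with NA)",
            unmatched))
    out <- data.frame(gene_id = h$gene_id, totalHops = h$totalHops,
                      nPeaks = h$nPeaks, logFC = e$logFC[i],
                      pAdj = e$pAdj[i])
    out$isTarget <- out$totalHops > hopThreshold
    out$isResponsive <- !is.na(out$pAdj) & out$pAdj <= pThreshold
    out$isStrong <- out$isResponsive & !is.na(out$logFC) &
        abs(out$logFC) > log2(foldThreshold)
    out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of every table whose probability
#' does not exceed that of the observed table (within a relative tolerance
#' of 1e-7, matching the conventional definition). Degenerate margins
#' (an all-zero row or column) give p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))  # 1
#' @export
fisherExact2x2 <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L)))
        stop("'tab' must be a 2x2 table")
    if (any(tab < 0) || any(tab != floor(tab)))
        stop("table entries must be non-negative integers")
    r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
    if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2L]) == 0)
        return(1)
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    pObs <- dhyper(tab[1L, 1L], r1, r2, c1)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Association between insertion burden and expression response
#'
#' Tests whether genes with more than `hopThreshold` insertions are
#' enriched for expression responses (adjusted p <= `pThreshold`) relative
#' to genes with at least one but no more than `hopThreshold` insertions.
#' Genes with zero hops, or lacking expression data, are excluded and
#' counted.
#'
#' @param records output of [buildGeneTargetTable()].
#' @param hopThreshold,pThreshold thresholds as in
#'   [buildGeneTargetTable()].
#' @return list with `table` (2x2: hops > / <= threshold x responsive /
#'   not), `pValue` (two-sided Fisher), `responsiveFractionHigh`,
#'   `responsiveFractionLow`, `nExcluded`.
#' @export
associationTest <- function(records, hopThreshold = 5, pThreshold = 0.01) {
    keep <- records$totalHops >= 1 & !is.na(records$pAdj)
    nExcluded <- sum(!keep)
    rec <- records[keep, , drop = FALSE]
    if (!nrow(rec))
        stop("no genes with hops and expression data to test")
    hi <- rec$totalHops > hopThreshold
    resp <- rec$pAdj <= pThreshold
    tab <- matrix(c(sum(hi & resp), sum(hi & !resp),
                    sum(!hi & resp), sum(!hi & !resp)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(
                      hops = c(sprintf("> %g", hopThreshold),
                               sprintf("1..%g", hopThreshold)),
                      expression = c("responsive", "not responsive")))
    list(table = tab,
         pValue = fisherExact2x2(tab),
         responsiveFractionHigh = if (sum(hi)) mean(resp[hi]) else NA_real_,
         responsiveFractionLow = if (sum(!hi)) mean(resp[!hi]) else NA_real_,
         nExcluded = nExcluded)
}

#' Select strong responsive target genes
#'
#' Genes combining heavy insertion targeting (total hops >
#' `hopThreshold`), a significant expression response (adjusted p <=
#' `pThreshold`) and a linear fold change above `foldThreshold`,
#' partitioned into up- and down-regulated lists by the sign of the log
#' fold change.
#'
#' @param records output of [buildGeneTargetTable()].
#' @param hopThreshold,pThreshold,foldThreshold selection thresholds.
#' @return list with `table` (the selected records with a `direction`
#'   column), `up` and `down` (gene-id vectors).
#' @export
selectStrongTargets <- function(records, hopThreshold = 5,
                                pThreshold = 0.01, foldThreshold = 2) {
    sel <- records$totalHops > hopThreshold &
        !is.na(records$pAdj) & records$pAdj <= pThreshold &
        !is.na(records$logFC) & abs(records$logFC) > log2(foldThreshold)
    tab <- records[sel, , drop = FALSE]
    tab$direction <- ifelse(tab$logFC > 0, "up", "down")
    rownames(tab) <- NULL
    list(table = tab,
         up = tab$gene_id[tab$direction == "up"],
         down = tab$gene_id[tab$direction == "down"])
}

#' Write a gene-target table
#'
#' TSV mirroring the per-gene report: gene, linear fold change, adjusted
#' p, hops, peaks and selection flags.
#'
#' @param records output of [buildGeneTargetTable()] (optionally with a
#'   `direction` column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTargetTable <- function(records, path) {
    out <- records
    out$foldChange <- ifelse(is.na(out$logFC), NA, 2^abs(out$logFC) *
                             sign(out$logFC))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
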