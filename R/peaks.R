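## Poisson peak calling of foreground hops against a background library,
## with the expected hops-per-TTAA rate estimated locally as the maximum
## over three nested windows around each peak.

#' Peak-calling parameters
#'
#' Bundles the tunable parameters of [callPeaks()].
#'
#' @param maxGap maximum distance in bp between consecutive hops of one
#'   cluster (single-linkage 1-D clustering); default 5000.
#' @param flankSmall,flankLarge half-width extensions in bp of the second
#'   and third background windows around the peak midpoint (defaults 1000
#'   and 5000). The three windows are: the peak span itself, the span
#'   extended by `flankSmall`, and by `flankLarge`; the background rate is
#'   the maximum of the three.
#' @param minHops minimum hops for a cluster to become a candidate peak and
#'   enter multiple testing; default 2 (singleton clusters are reported but
#'   never significant — sparse loci are unclustered background).
#' @param fdrAlpha Benjamini-Hochberg FDR threshold for significance.
#' @param depthScale scale the background rate by the foreground/background
#'   total-hop ratio; default `TRUE` (enrichment across libraries of
#'   different depth is meaningless without it).
#' @param bgFloor floor on the background hop count of each window before
#'   rate computation; default 1. Prevents lambda = 0 (hence p = 0)
#'   artifacts in background deserts.
#' @return a validated list of class `PeakCallParams`.
#' @export
peakCallParams <- function(maxGap = 5000, flankSmall = 1000,
                           flankLarge = 5000, minHops = 2L,
                           fdrAlpha = 0.05, depthScale = TRUE,
                           bgFloor = 1) {
    stopifnot(maxGap >= 0, flankSmall >= 0, flankLarge >= 0,
              minHops >= 1, fdrAlpha > 0, fdrAlpha < 1, bgFloor >= 0)
    structure(list(maxGap = maxGap, flankSmall = flankSmall,
                   flankLarge = flankLarge, minHops = as.integer(minHops),
                   fdrAlpha = fdrAlpha, depthScale = isTRUE(depthScale),
                   bgFloor = bgFloor),
              class = "PeakCallParams")
}

#' Single-linkage 1-D clustering of hop positions
#'
#' Groups sorted positions so that consecutive positions at most `maxGap`
#' apart share a group; groups are maximal (the transitive closure of the
#' "gap <= maxGap" relation) and every position belongs to exactly one.
#'
#' @param positions sorted (ascending) numeric positions; duplicates allowed.
#' @param maxGap maximum within-cluster gap in bp.
#' @return list of integer/numeric vectors, one per cluster, in order.
#' @examples
#' clusterInsertions(c(100, 3000, 9000), maxGap = 5000)
#' @export
clusterInsertions <- function(positions, maxGap = 5000) {
    if (is.unsorted(positions))
        stop("'positions' must be sorted ascending")
    if (!length(positions)) return(list())
    grp <- cumsum(c(1L, as.integer(diff(positions) > maxGap)))
    unname(split(positions, grp))
}

#' Genomic span of a hop cluster
#'
#' The 0-based half-open interval from the first TTAA to the end of the
#' last: `[min, max + 4)`, so the final tetranucleotide is covered and
#' every span is at least 4 bp.
#'
#' @param group non-empty vector of 0-based hop positions.
#' @return numeric `c(start, end)`.
#' @export
peakSpan <- function(group) {
    if (!length(group)) stop("empty cluster has no span")
    c(min(group), max(group) + 4)
}

#' Locally estimated expected hops under the background model
#'
#' Estimates the Poisson mean for a peak from the background library. Three
#' windows are centered on the peak midpoint: the peak span itself and the
#' span widened by `flankSmall` and `flankLarge` on each side, clipped to
#' the chromosome. In each window the background rate is
#' `max(background hops, bgFloor) / TTAA sites`; windows without TTAA sites
#' are skipped. The expected count is
#' `depthRatio * max(rates) * (TTAA sites under the peak)`; if every window
#' lacks TTAA sites, `depthRatio * bgFloor`. Taking the maximum of nested
#' local estimates guards against underestimating the background in
#' regions of uneven insertion density.
#'
#' @param chromosome chromosome of the peak.
#' @param start,end 0-based half-open peak span.
#' @param bgPositions sorted 0-based background hop positions on that
#'   chromosome (with multiplicity).
#' @param index a [TTAAIndex-class].
#' @param params a [peakCallParams()] list.
#' @param depthRatio foreground/background total-hop ratio.
#' @return the expected hop count lambda (non-negative scalar).
#' @export
estimateLambda <- function(chromosome, start, end, bgPositions, index,
                           params = peakCallParams(), depthRatio = 1) {
    stopifnot(start < end)
    if (is.unsorted(bgPositions))
        stop("'bgPositions' must be sorted")
    len <- seqlengths(index)[[chromosome]]
    if (is.null(len) || is.na(len)) len <- Inf
    mid <- (start + end) / 2
    half <- (end - start) / 2
    nPeak <- countTTAA(index, chromosome, start, end)
    best <- -Inf
    for (h in c(half, half + params$flankSmall, half + params$flankLarge)) {
        lo <- max(0, floor(mid - h))
        hi <- min(len, ceiling(mid + h))
        nT <- countTTAA(index, chromosome, lo, hi)
        if (nT == 0L) next
        nBg <- findInterval(hi - 0.5, bgPositions) -
            findInterval(lo - 0.5, bgPositions)
        best <- max(best, max(nBg, params$bgFloor) / nT)
    }
    if (!is.finite(best))
        return(depthRatio * params$bgFloor)
    depthRatio * best * nPeak
}

#' Poisson upper-tail probability
#'
#' P(X >= k) for X ~ Poisson(lambda), the enrichment p-value of a peak with
#' k observed hops and expected count lambda. Computed through the
#' regularized incomplete gamma function (via [stats::ppois()]), which is
#' stable far into the tail.
#'
#' @param k observed count(s), non-negative integer.
#' @param lambda expected count(s), non-negative.
#' @return upper-tail probabilities in `[0, 1]`.
#' @examples
#' poissonUpperTail(2, 2)  # 1 - e^-2 * 3 = 0.5940
#' @export
poissonUpperTail <- function(k, lambda) {
    if (any(k < 0) || any(k != floor(k)))
        stop("'k' must be a non-negative integer")
    if (any(lambda < 0)) stop("'lambda' must be non-negative")
    ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-aligned with the input.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, elementwise >= p.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Call peaks of foreground hops against a background library
#'
#' Clusters deduplicated foreground hops per chromosome (maximum inter-hop
#' gap `maxGap`), computes for every cluster the TTAA content, the locally
#' estimated background expectation ([estimateLambda()]) and the Poisson
#' upper-tail p-value, then applies Benjamini-Hochberg correction across
#' all candidate clusters (those with at least `minHops` hops). A peak is
#' significant when its q-value is at most `fdrAlpha`. Sub-threshold
#' clusters are retained in the output with `candidate = FALSE` and an NA
#' q-value; they never reach significance.
#'
#' The method requires a background library (insertions of the unfused
#' transposase): it is the empirical model of where the transposase lands
#' without a fusion partner.
#'
#' @param fg,bg foreground and background [InsertionSet-class]s,
#'   deduplicated with [dedupHops()].
#' @param index a [TTAAIndex-class] for the same genome.
#' @param params a [peakCallParams()] list.
#' @return a [CalledPeaks-class], coordinate-sorted.
#' @export
callPeaks <- function(fg, bg, index, params = peakCallParams()) {
    stopifnot(is(fg, "InsertionSet"), is(bg, "InsertionSet"),
              is(index, "TTAAIndex"))
    if (!length(bg))
        stop("background library is empty; the enrichment test requires one")
    empty <- GRanges(seqlengths = seqlengths(index))
    mcols(empty) <- DataFrame(hops = integer(), nTTAA = integer(),
                              lambda = numeric(), pValue = numeric(),
                              qValue = numeric(), candidate = logical(),
                              significant = logical())
    if (!length(fg)) return(new("CalledPeaks", empty))
    depthRatio <- if (params$depthScale) length(fg) / length(bg) else 1
    fgChrom <- as.character(seqnames(fg))
    fgPos <- start(fg) - 1L
    bgChrom <- as.character(seqnames(bg))
    bgPos <- start(bg) - 1L
    rows <- list()
    for (chrom in sort(unique(fgChrom))) {
        pos <- sort(fgPos[fgChrom == chrom])
        bgc <- sort(bgPos[bgChrom == chrom])
        groups <- clusterInsertions(pos, params$maxGap)
        spans <- vapply(groups, peakSpan, numeric(2))
        k <- lengths(groups)
        lam <- vapply(seq_along(groups), function(i)
            estimateLambda(chrom, spans[1L, i], spans[2L, i], bgc, index,
                           params, depthRatio), numeric(1))
        nT <- countTTAA(index, chrom, spans[1L, ], spans[2L, ])
        rows[[chrom]] <- data.frame(
            chrom = chrom, start = spans[1L, ], end = spans[2L, ],
            hops = k, nTTAA = nT, lambda = lam,
            pValue = poissonUpperTail(k, lam))
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
    cand <- tab$hops >= params$minHops
    q <- rep(NA_real_, nrow(tab))
    if (any(cand)) q[cand] <- bhAdjust(tab$pValue[cand])
    knownChrom <- tab$chrom %in% names(seqlengths(index))
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
    if (all(knownChrom))
        seqlengths(gr) <- seqlengths(index)[seqlevels(gr)]
    mcols(gr) <- DataFrame(
        hops = tab$hops, nTTAA = tab$nTTAA, lambda = tab$lambda,
        pValue = tab$pValue, qValue = q, candidate = cand,
        significant = cand & !is.na(q) & q <= params$fdrAlpha)
    new("CalledPeaks", gr)
}

#' Histogram of hops per locus
#'
#' Frequency table of hop counts across peaks/clusters: how many genomic
#' loci carry each number of insertions. Loci with few hops dominate in an
#' untargeted library, while a fused transposase produces a long tail of
#' heavily targeted loci.
#'
#' @param x a [CalledPeaks-class] or an integer vector of per-locus hop
#'   counts.
#' @return `data.frame(hops, loci)` sorted by hops; zero rows when empty.
#' @export
hopCountHistogram <- function(x) {
    if (is(x, "CalledPeaks")) x <- mcols(x)$hops
    if (!length(x))
        return(data.frame(hops = integer(), loci = integer()))
    tab <- table(x)
    data.frame(hops = as.integer(names(tab)), loci = as.integer(tab))
}

#' Write a peak table
#'
#' BED6+ layout: chrom, start, end, name, hops, strand ("."), then
#' nTTAA, lambda, pValue, qValue, significant (and any annotation columns
#' added by [annotatePeaks()]), tab-delimited with a header line starting
#' with '#'.
#'
#' @param peaks a [CalledPeaks-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
    stopifnot(is(peaks, "CalledPeaks"))
    md <- as.data.frame(mcols(peaks))
    tab <- data.frame(
        chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L,
        end = end(peaks),
        name = if (length(peaks)) sprintf("peak_%05d", seq_along(peaks))
               else character(),
        hops = md$hops,
        strand = rep(".", length(peaks)))
    tab <- cbind(tab, md[setdiff(colnames(md), "hops")])
    header <- paste0("#", paste(colnames(tab), collapse = "\t"))
    writeLines(header, path)
    suppressWarnings(write.table(tab, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = FALSE,
                                 append = TRUE))
    invisible(path)
}

#' Read a peak table written by [writePeaks()]
#'
#' @param path file written by [writePeaks()].
#' @return a [CalledPeaks-class].
#' @export
readPeaks <- function(path) {
    header <- sub("^#", "", readLines(path, n = 1L))
    cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
    tab <- read.table(path, sep = "\t", skip = 1L, col.names = cols,
                      stringsAsFactors = FALSE, na.strings = "NA")
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
    keep <- setdiff(cols, c("chrom", "start", "end", "name", "strand"))
    md <- tab[keep]
    front <- intersect(c("hops", "nTTAA", "lambda", "pValue", "qValue",
                         "candidate", "significant"), colnames(md))
    md <- md[c(front, setdiff(colnames(md), front))]
    mcols(gr) <- as(md, "DataFrame")
    new("CalledPeaks", gr)
}
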