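## nearest-gene / TSS annotation and distance statistics:
## closest-interval semantics with deterministic tie-breaks, Mann-Whitney
## rank tests, random-position controls, and overlap (Venn) summaries.

#' Nearest gene for each peak
#'
#' bedtools-closest semantics: for each query interval, the gene minimizing
#' the interval distance (0 when the intervals overlap; otherwise the gap
#' in bp). Ties are broken deterministically by smaller gene start, then
#' lexicographic `gene_id`. Queries on chromosomes without genes are
#' annotated NA with a warning.
#'
#' @param x query [GenomicRanges::GRanges] (peaks, insertions, positions).
#' @param genes [GenomicRanges::GRanges] with a `gene_id` column.
#' @return `data.frame(gene_id, distance)`, one row per query.
#' @export
nearestFeature <- function(x, genes) {
    stopifnot(is(x, "GRanges"), is(genes, "GRanges"),
              !is.null(mcols(genes)$gene_id))
    if (!length(genes)) stop("'genes' is empty")
    ids <- rep(NA_character_, length(x))
    dists <- rep(NA_integer_, length(x))
    if (!length(x))
        return(data.frame(gene_id = ids, distance = dists))
    ## strand- and seqlevel-agnostic copies; distanceToNearest gives the
    ## minimum distance, a second overlap pass recovers *all* genes at
    ## that distance so the documented tie-break can apply
    lv <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(genes))
    xs <- GRanges(factor(as.character(seqnames(x)), lv),
                  IRanges(start(x), end(x)))
    gs <- GRanges(factor(as.character(seqnames(genes)), lv),
                  IRanges(start(genes), end(genes)))
    dn <- GenomicRanges::distanceToNearest(xs, gs)
    dmin <- rep(NA_integer_, length(x))
    dmin[queryHits(dn)] <- mcols(dn)$distance
    hits <- findOverlaps(xs, gs,
                         maxgap = max(c(0L, dmin), na.rm = TRUE))
    if (length(hits)) {
        d <- GenomicRanges::distance(xs[queryHits(hits)],
                                     gs[subjectHits(hits)])
        keep <- !is.na(dmin[queryHits(hits)]) &
            d == dmin[queryHits(hits)]
        hits <- hits[keep]; d <- d[keep]
    }
    if (length(hits)) {
        hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits), d = d)
        hdf$gstart <- start(genes)[hdf$s]
        hdf$gid <- mcols(genes)$gene_id[hdf$s]
        hdf <- hdf[order(hdf$q, hdf$d, hdf$gstart, hdf$gid), , drop = FALSE]
        hdf <- hdf[!duplicated(hdf$q), , drop = FALSE]
        ids[hdf$q] <- hdf$gid
        dists[hdf$q] <- as.integer(hdf$d)
    }
    if (anyNA(ids))
        warning(sprintf(
            "%d region(s) on chromosomes without genes; annotated NA",
            sum(is.na(ids))))
    data.frame(gene_id = ids, distance = dists)
}

#' Distance from each region midpoint to the nearest TSS
#'
#' For each query region the midpoint is `floor((start + end) / 2)` in
#' 0-based coordinates; the distance is the minimum over same-chromosome
#' genes of |midpoint - TSS|, with the TSS taken strand-aware ([tssOf()]).
#' Regions on chromosomes without genes give NA with a warning.
#'
#' @param x query [GenomicRanges::GRanges] (peaks, insertions, or
#'   [randomPositions()] output).
#' @param genes [GenomicRanges::GRanges] with `gene_id` and +/- strand.
#' @param signed return the signed offset midpoint - TSS of the nearest
#'   TSS instead of its absolute value.
#' @return numeric vector, one distance per query.
#' @export
tssDistances <- function(x, genes, signed = FALSE) {
    stopifnot(is(x, "GRanges"), is(genes, "GRanges"))
    if (!length(genes)) stop("'genes' is empty")
    tss <- tssOf(genes)
    gchrom <- as.character(seqnames(genes))
    mids <- floor((start(x) - 1 + end(x)) / 2)
    chroms <- as.character(seqnames(x))
    out <- rep(NA_real_, length(x))
    for (chrom in unique(chroms)) {
        tc <- sort(tss[gchrom == chrom])
        sel <- chroms == chrom
        if (!length(tc)) next
        m <- mids[sel]
        i <- findInterval(m, tc)
        lo <- tc[pmax(i, 1L)]               # nearest at or below (clamped)
        hi <- tc[pmin(i + 1L, length(tc))]  # nearest above (clamped)
        dlo <- ifelse(i >= 1L, m - lo, Inf)
        dhi <- ifelse(i < length(tc), hi - m, Inf)
        nearestT <- ifelse(dlo <= dhi, lo, hi)  # tie -> smaller TSS
        out[sel] <- if (signed) m - nearestT else abs(m - nearestT)
    }
    if (anyNA(out))
        warning(sprintf(
            "%d region(s) on chromosomes without genes; distance NA",
            sum(is.na(out))))
    out
}

#' Mann-Whitney U rank-sum test
#'
#' U is computed from midranks (ties allowed). For pooled sample sizes
#' n1 + n2 <= 16 the p-value comes from exact enumeration of all
#' assignments of the observed pooled values to the two groups — valid
#' under ties, where the classical exact tables are not. For larger
#' samples the normal approximation with tie correction and continuity
#' correction is used. `alternative = "less"` tests whether `a` tends to
#' be smaller than `b` (e.g. peak TSS distances smaller than random).
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return a `RankTestResult` list: `U` (statistic for sample `a`), `n1`,
#'   `n2`, `pValue`, `alternative`, `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$pValue  # 0.1, exact
#' @export
mannWhitneyU <- function(a, b,
                         alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b))
        stop("both samples must be non-empty")
    n1 <- length(a); n2 <- length(b); N <- n1 + n2
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (N <= 16L) {
        sets <- utils::combn(N, n1)
        Uperm <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
        eps <- 1e-9
        pLess <- mean(Uperm <= U + eps)
        pGreater <- mean(Uperm >= U - eps)
        method <- "exact enumeration"
    } else {
        ties <- table(r)
        mu <- n1 * n2 / 2
        sig2 <- n1 * n2 / 12 *
            ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        if (sig2 <= 0) {
            pLess <- pGreater <- 1
        } else {
            sig <- sqrt(sig2)
            pLess <- pnorm((U - mu + 0.5) / sig)
            pGreater <- pnorm((U - mu - 0.5) / sig, lower.tail = FALSE)
        }
        method <- "normal approximation, tie and continuity corrected"
    }
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pLess, pGreater)),
                less = pLess,
                greater = pGreater)
    structure(list(U = U, n1 = n1, n2 = n2, pValue = p,
                   alternative = alternative, method = method),
              class = "RankTestResult")
}

#' @export
print.RankTestResult <- function(x, ...) {
    cat(sprintf("Mann-Whitney U test (%s)\n", x$method))
    cat(sprintf("  U = %g (n1 = %d, n2 = %d), %s p = %.4g\n",
                x$U, x$n1, x$n2, x$alternative, x$pValue))
    invisible(x)
}

#' Random genomic positions
#'
#' Draws positions uniformly over the concatenated genome: the chromosome
#' is chosen proportional to its length, the position uniformly within it.
#' Used as the random-region control for TSS-distance comparisons. The
#' seed is recorded in the metadata of the result.
#'
#' @param chromLengths named chromosome lengths in bp.
#' @param n number of positions.
#' @param seed integer seed; the draw is a pure function of it.
#' @return width-1 [GenomicRanges::GRanges] of positions.
#' @export
randomPositions <- function(chromLengths, n, seed) {
    stopifnot(n >= 1, sum(as.numeric(chromLengths)) > 0,
              !is.null(names(chromLengths)))
    withr::with_seed(seed, {
        chrom <- sample(names(chromLengths), n, replace = TRUE,
                        prob = as.numeric(chromLengths))
        pos <- floor(runif(n) * chromLengths[chrom])
    })
    gr <- GRanges(chrom, IRanges(pos + 1, width = 1))
    seqlengths(gr) <- chromLengths[seqlevels(gr)]
    S4Vectors::metadata(gr)$seed <- seed
    gr
}

#' Annotate peaks with nearest gene and TSS distance
#'
#' Appends `nearestGene`, `geneDistance` (interval distance to the nearest
#' gene, 0 when overlapping), `tssDistance` (|midpoint - nearest TSS|) and
#' `tssOffset` (the signed midpoint - TSS, kept for stranded reporting)
#' to a peak set.
#'
#' @param peaks a [CalledPeaks-class].
#' @param genes [GenomicRanges::GRanges] with `gene_id` and strand.
#' @return the annotated [CalledPeaks-class].
#' @export
annotatePeaks <- function(peaks, genes) {
    stopifnot(is(peaks, "CalledPeaks"))
    nf <- nearestFeature(peaks, genes)
    mcols(peaks)$nearestGene <- nf$gene_id
    mcols(peaks)$geneDistance <- nf$distance
    mcols(peaks)$tssDistance <- tssDistances(peaks, genes)
    mcols(peaks)$tssOffset <- tssDistances(peaks, genes, signed = TRUE)
    peaks
}

#' Interval-overlap Venn summary of two peak sets
#'
#' A peak is "shared" when it intersects at least one peak of the other
#' set by at least 1 bp (optionally at least `minFraction` of its own
#' width). Because peak boundaries differ between sets, shared counts are
#' reported from each side, together with the number of overlapping pairs.
#'
#' @param a,b two [GenomicRanges::GRanges]/[CalledPeaks-class] sets.
#' @param minFraction minimum overlap as a fraction of the query peak
#'   width (default 0: any 1 bp overlap counts).
#' @return list with `onlyA`, `sharedA`, `sharedB`, `onlyB`,
#'   `sharedPairs`.
#' @export
intervalOverlapVenn <- function(a, b, minFraction = 0) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"),
              minFraction >= 0, minFraction <= 1)
    hits <- findOverlaps(a, b, ignore.strand = TRUE)
    if (minFraction > 0 && length(hits)) {
        ow <- width(IRanges::pintersect(
            IRanges::ranges(a)[queryHits(hits)],
            IRanges::ranges(b)[subjectHits(hits)]))
        keepA <- ow / width(a)[queryHits(hits)] >= minFraction
        keepB <- ow / width(b)[subjectHits(hits)] >= minFraction
        sharedA <- length(unique(queryHits(hits)[keepA]))
        sharedB <- length(unique(subjectHits(hits)[keepB]))
        pairs <- sum(keepA | keepB)
    } else {
        sharedA <- length(unique(queryHits(hits)))
        sharedB <- length(unique(subjectHits(hits)))
        pairs <- length(hits)
    }
    list(onlyA = length(a) - sharedA, sharedA = sharedA,
         sharedB = sharedB, onlyB = length(b) - sharedB,
         sharedPairs = pairs)
}

#' Gene-set Venn summary of two constructs
#'
#' Exact set algebra on two gene-id sets; the union is retained because
#' downstream expression integration pools targets of the two fusion
#' orientations.
#'
#' @param genesA,genesB character vectors of gene ids.
#' @return list with `onlyA`, `shared`, `onlyB` (character vectors),
#'   `union`, and `counts` (named integer vector).
#' @export
geneSetVenn <- function(genesA, genesB) {
    genesA <- unique(as.character(genesA))
    genesB <- unique(as.character(genesB))
    shared <- intersect(genesA, genesB)
    onlyA <- setdiff(genesA, genesB)
    onlyB <- setdiff(genesB, genesA)
    list(onlyA = onlyA, shared = shared, onlyB = onlyB,
         union = union(genesA, genesB),
         counts = c(onlyA = length(onlyA), shared = length(shared),
                    onlyB = length(onlyB)))
}

#' Bin TSS distances for histogram export
#'
#' Fixed-width bins over a symmetric range (signed offsets) or from zero
#' (absolute distances); values outside the range are dropped.
#'
#' @param distances numeric distances or signed offsets in bp.
#' @param binWidth bin width in bp (default 500).
#' @param range half-range in bp (default 50000).
#' @return `data.frame(bin_start, count)`.
#' @export
tssDistanceHistogram <- function(distances, binWidth = 500, range = 50000) {
    distances <- distances[!is.na(distances)]
    breaks <- if (any(distances < 0))
        seq(-range, range, by = binWidth)
    else seq(0, range, by = binWidth)
    distances <- distances[distances >= breaks[1L] &
                           distances < breaks[length(breaks)]]
    bin <- breaks[findInterval(distances, breaks)]
    counts <- table(factor(bin, levels = breaks[-length(breaks)]))
    data.frame(bin_start = as.numeric(names(counts)),
               count = as.integer(counts))
}
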