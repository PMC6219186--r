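#' TTAAIndex: indexed TTAA tetranucleotide positions of a genome
#'
#' Holds, for each chromosome, the sorted 0-based start positions of every
#' TTAA tetranucleotide, together with chromosome lengths. piggyBac
#' transposons integrate only at TTAA sites, so this index provides the
#' denominator for the hops-per-TTAA background rate used in peak calling.
#'
#' Positions follow the BED convention (0-based, half-open intervals), so the
#' index interoperates bit-exactly with qBED insertion files and BED exports.
#'
#' @slot sites named list of strictly increasing integer vectors, one per
#'   chromosome; each value is the 0-based position of the first T of a TTAA.
#' @slot seqlengths named integer vector of chromosome lengths in bp.
#'
#' @seealso [ttaaIndex()], [scanTTAA()], [countTTAA()]
#' @export
setClass("TTAAIndex",
    representation(sites = "list", seqlengths = "integer"))

setValidity("TTAAIndex", function(object) {
    msgs <- character()
    if (is.null(names(object@sites)) || is.null(names(object@seqlengths)))
        msgs <- c(msgs, "'sites' and 'seqlengths' must be named")
    if (!identical(names(object@sites), names(object@seqlengths)))
        msgs <- c(msgs, "names of 'sites' and 'seqlengths' must match")
    for (chrom in names(object@sites)) {
        p <- object@sites[[chrom]]
        len <- object@seqlengths[[chrom]]
        if (!is.integer(p))
            msgs <- c(msgs, sprintf("positions on %s are not integer", chrom))
        else {
            if (is.unsorted(p, strictly = TRUE))
                msgs <- c(msgs, sprintf(
                    "positions on %s are not strictly increasing", chrom))
            if (length(p) && (p[1L] < 0L || p[length(p)] > len - 4L))
                msgs <- c(msgs, sprintf(
                    "positions on %s fall outside [0, length-4]", chrom))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' InsertionSet: deduplicated transposon insertion events ("hops")
#'
#' A [GenomicRanges::GRanges] subclass in which each range is the 4 bp TTAA
#' tetranucleotide into which a transposon inserted. Metadata columns record
#' the donor barcode, the supporting read count, and the sample identifier.
#' One row after [dedupHops()] is one independent integration event (a
#' "hop"): the unit counted by the peak-calling statistics.
#'
#' @seealso [readQbed()], [dedupHops()], [callPeaks()]
#' @export
setClass("InsertionSet", contains = "GRanges")

setValidity("InsertionSet", function(object) {
    msgs <- character()
    need <- c("barcode", "reads", "sampleID")
    missing <- setdiff(need, colnames(mcols(object)))
    if (length(missing))
        return(sprintf("missing metadata column(s): %s",
                       paste(missing, collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 4L))
            msgs <- c(msgs, "all insertion ranges must be 4 bp (a TTAA)")
        if (any(mcols(object)$reads < 1L))
            msgs <- c(msgs, "read support must be >= 1")
        if (any(!as.character(strand(object)) %in% c("+", "-")))
            msgs <- c(msgs, "strand must be '+' or '-'")
    }
    if (length(msgs)) msgs else TRUE
})

#' CalledPeaks: clusters of hops tested for Poisson enrichment
#'
#' A [GenomicRanges::GRanges] subclass holding the peak-caller output. Each
#' range spans a cluster of foreground hops (maximum inter-hop gap
#' `maxGap`), from the first TTAA to the end of the last. Metadata columns:
#'
#' * `hops` — observed foreground hops k in the cluster;
#' * `nTTAA` — TTAA sites under the peak span;
#' * `lambda` — expected hops under the background model;
#' * `pValue` — Poisson upper tail P(X >= k | lambda);
#' * `qValue` — Benjamini-Hochberg adjusted p (NA for non-candidates);
#' * `candidate` — cluster has at least `minHops` hops and entered testing;
#' * `significant` — candidate with qValue <= fdrAlpha.
#'
#' [annotatePeaks()] appends `nearestGene`, `geneDistance` and `tssDistance`.
#'
#' @seealso [callPeaks()], [annotatePeaks()]
#' @export
setClass("CalledPeaks", contains = "GRanges")

setValidity("CalledPeaks", function(object) {
    need <- c("hops", "nTTAA", "lambda", "pValue", "qValue",
              "candidate", "significant")
    missing <- setdiff(need, colnames(mcols(object)))
    if (length(missing))
        return(sprintf("missing metadata column(s): %s",
                       paste(missing, collapse = ", ")))
    msgs <- character()
    if (length(object)) {
        p <- mcols(object)$pValue
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msgs <- c(msgs, "pValue outside [0, 1]")
        q <- mcols(object)$qValue
        if (any(q < p - 1e-12, na.rm = TRUE))
            msgs <- c(msgs, "qValue must be >= pValue")
        if (any(mcols(object)$hops < 1L))
            msgs <- c(msgs, "every peak must contain at least one hop")
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "TTAAIndex", function(object) {
    cat(sprintf("TTAAIndex: %d sequence(s), %s TTAA site(s), %s bp\n",
                length(object@sites),
                format(sum(lengths(object@sites)), big.mark = ","),
                format(sum(as.numeric(object@seqlengths)), big.mark = ",")))
    for (chrom in utils::head(names(object@sites), 5L))
        cat(sprintf("  %s: %s sites / %s bp\n", chrom,
                    format(length(object@sites[[chrom]]), big.mark = ","),
                    format(object@seqlengths[[chrom]], big.mark = ",")))
    if (length(object@sites) > 5L)
        cat(sprintf("  ... and %d more\n", length(object@sites) - 5L))
})
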