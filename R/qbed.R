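## calling-card insertion I/O: qBED-style tables and hop deduplication.

#' Construct an InsertionSet
#'
#' @param chromosome character vector of chromosome names.
#' @param pos integer vector of 0-based TTAA start positions.
#' @param strand `"+"` or `"-"` per insertion.
#' @param barcode donor barcode per insertion.
#' @param reads supporting read count (>= 1), recycled.
#' @param sampleID sample label, recycled.
#' @param seqlengths optional named chromosome lengths.
#' @return an [InsertionSet-class].
#' @examples
#' InsertionSet("chr1", 100L, "+", "BC01", reads = 7L)
#' @export
InsertionSet <- function(chromosome = character(), pos = integer(),
                         strand = character(), barcode = character(),
                         reads = 1L, sampleID = "sample",
                         seqlengths = NULL) {
    n <- length(pos)
    if (any(pos < 0L)) stop("insertion positions must be >= 0")
    gr <- GRanges(chromosome, IRanges(start = pos + 1L, width = 4L),
                  strand = rep_len(strand, n))
    mcols(gr)$barcode <- rep_len(as.character(barcode), n)
    mcols(gr)$reads <- rep_len(as.integer(reads), n)
    mcols(gr)$sampleID <- rep_len(as.character(sampleID), n)
    if (!is.null(seqlengths))
        seqlengths(gr) <- seqlengths[seqlevels(gr)]
    new("InsertionSet", gr)
}

#' 0-based TTAA positions of insertions
#'
#' @param x an [InsertionSet-class].
#' @return integer vector of 0-based positions (BED convention).
#' @export
hopPositions <- function(x) {
    stopifnot(is(x, "InsertionSet"))
    start(x) - 1L
}

#' Read a qBED-style insertion table
#'
#' Parses the tab-delimited calling-card interchange format with columns
#' chrom, start, end, reads, strand, barcode (no header; BED-style 0-based
#' half-open coordinates). Records whose interval is not 4 bp wide are
#' coerced to `[start, start+4)` with a warning, tolerating 1 bp
#' "insertion point" dialects.
#'
#' If a [TTAAIndex-class] is supplied, positions that do not coincide with
#' an indexed TTAA site are reported: a warning by default, an error when
#' `strict = TRUE`. Real pipelines emit occasional off-TTAA artifacts, so
#' the default keeps them.
#'
#' @param path tab-delimited file.
#' @param sampleID sample label attached to every record.
#' @param ttaa optional [TTAAIndex-class] used to validate positions.
#' @param strict error (rather than warn) on off-TTAA positions.
#' @return an [InsertionSet-class] in file order.
#' @export
readQbed <- function(path, sampleID = "sample", ttaa = NULL,
                     strict = FALSE) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(InsertionSet(sampleID = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 6L))
        stop(sprintf("line %d: expected 6 tab-separated columns, found %d",
                     which(nf < 6L)[1L], nf[which(nf < 6L)[1L]]))
    m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    reads <- suppressWarnings(as.integer(m[, 4L]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop(sprintf("line %d: non-integer coordinates", bad[1L]))
    bad <- which(is.na(reads) | reads < 1L)
    if (length(bad))
        stop(sprintf("line %d: read count must be an integer >= 1", bad[1L]))
    badw <- which(end - start != 4L)
    if (length(badw)) {
        warning(sprintf(
            "%d record(s) not 4 bp wide; coerced to [start, start+4)",
            length(badw)))
    }
    if (any(!m[, 5L] %in% c("+", "-")))
        stop(sprintf("line %d: strand must be '+' or '-'",
                     which(!m[, 5L] %in% c("+", "-"))[1L]))
    ins <- InsertionSet(m[, 1L], start, m[, 5L], m[, 6L], reads, sampleID)
    if (!is.null(ttaa)) {
        off <- vapply(seq_along(ins), function(i) {
            s <- ttaaSites(ttaa, as.character(seqnames(ins)[i]))
            is.null(s) || !(start(ins)[i] - 1L) %in% s
        }, logical(1))
        if (any(off)) {
            msg <- sprintf("%d insertion(s) not at an indexed TTAA site",
                           sum(off))
            if (strict) stop(msg) else warning(msg)
        }
    }
    ins
}

#' Write insertions as qBED
#'
#' Inverse of [readQbed()]: chrom, start, end, reads, strand, barcode,
#' tab-delimited without a header.
#'
#' @param x an [InsertionSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeQbed <- function(x, path) {
    stopifnot(is(x, "InsertionSet"))
    tab <- data.frame(
        chrom = as.character(seqnames(x)),
        start = start(x) - 1L,
        end = end(x),
        reads = mcols(x)$reads,
        strand = as.character(strand(x)),
        barcode = mcols(x)$barcode)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Deduplicate insertions into hops
#'
#' One hop is one independent transposition event, identified by the tuple
#' (chromosome, position, strand, barcode, sample). Repeated observations
#' of the same tuple — PCR and sequencing duplicates of a single event —
#' are collapsed to one record with their read counts summed. The result
#' is sorted by (chromosome, position) and is idempotent under repetition.
#'
#' @param x an [InsertionSet-class].
#' @return deduplicated, coordinate-sorted [InsertionSet-class].
#' @examples
#' x <- InsertionSet(c("chr1", "chr1"), c(100L, 100L), "+", "BC01",
#'                   reads = c(3L, 2L))
#' mcols(dedupHops(x))$reads  # 5
#' @export
dedupHops <- function(x) {
    stopifnot(is(x, "InsertionSet"))
    if (!length(x)) return(x)
    key <- paste(as.character(seqnames(x)), start(x),
                 as.character(strand(x)), mcols(x)$barcode,
                 mcols(x)$sampleID, sep = "\r")
    reads <- rowsum(as.numeric(mcols(x)$reads), key, reorder = FALSE)
    first <- !duplicated(key)
    out <- x[first]
    mcols(out)$reads <- as.integer(reads[match(key[first], rownames(reads)), 1L])
    ord <- order(as.character(seqnames(out)), start(out),
                 as.character(strand(out)), mcols(out)$barcode)
    new("InsertionSet", out[ord])
}

#' Export hops as BED for genome-browser use
#'
#' BED6 with the barcode as name and the read count as score.
#'
#' @param x an [InsertionSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportHopsBed <- function(x, path) {
    stopifnot(is(x, "InsertionSet"))
    tab <- data.frame(
        chrom = as.character(seqnames(x)),
        start = start(x) - 1L,
        end = end(x),
        name = mcols(x)$barcode,
        score = mcols(x)$reads,
        strand = as.character(strand(x)))
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
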