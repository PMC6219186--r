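## genome model: TTAA discovery/indexing and gene-model/TSS handling.
## All user-facing coordinates are BED-style: 0-based, half-open.

#' Find all TTAA tetranucleotide positions in a sequence
#'
#' Scans a nucleotide sequence for the piggyBac integration target TTAA and
#' returns the 0-based start position of every occurrence. Matching is
#' case-insensitive (soft-masked lowercase bases match) and any window
#' containing an N never matches. TTAA is its own reverse complement, so a
#' forward scan covers both strands.
#'
#' @param sequence a character string over A/C/G/T/N (either case), or a
#'   [Biostrings::DNAString].
#' @return sorted integer vector of 0-based match positions.
#' @examples
#' scanTTAA("GGTTAATTAACC")  # 2, 6
#' @export
scanTTAA <- function(sequence) {
    if (is.character(sequence)) {
        if (length(sequence) != 1L)
            stop("'sequence' must be a single string")
        bad <- regexpr("[^ACGTNacgtn]", sequence)
        if (bad > 0L)
            stop(sprintf(
                "non-nucleotide character '%s' at position %d (0-based %d)",
                substr(sequence, bad, bad), bad, bad - 1L))
        if (nchar(sequence) < 4L) return(integer())
        sequence <- DNAString(sequence)
    } else if (!is(sequence, "DNAString")) {
        stop("'sequence' must be a character string or DNAString")
    }
    if (length(sequence) < 4L) return(integer())
    start(matchPattern("TTAA", sequence, fixed = TRUE)) - 1L
}

#' Build a TTAA-site index for a genome
#'
#' Scans every sequence of a genome for TTAA sites and returns a
#' [TTAAIndex-class] recording their 0-based positions and the chromosome
#' lengths. The index supplies the per-TTAA denominator for the local
#' background rate in [callPeaks()].
#'
#' @param genome a named [Biostrings::DNAStringSet], or the path to a FASTA
#'   file (multi-record, wrapped lines).
#' @return a [TTAAIndex-class].
#' @examples
#' gs <- Biostrings::DNAStringSet(c(chr1 = "GGTTAACCTTAA"))
#' ttaaIndex(gs)
#' @export
ttaaIndex <- function(genome) {
    if (is.character(genome))
        genome <- readDNAStringSet(genome)
    if (!is(genome, "DNAStringSet"))
        stop("'genome' must be a DNAStringSet or a FASTA path")
    if (is.null(names(genome)))
        stop("genome sequences must be named")
    nm <- sub("\\s.*$", "", names(genome))  # FASTA ids: first token
    hits <- vmatchPattern("TTAA", genome, fixed = TRUE)
    sites <- lapply(hits, function(h) start(h) - 1L)
    names(sites) <- nm
    lens <- stats::setNames(Biostrings::width(genome), nm)
    new("TTAAIndex", sites = sites, seqlengths = lens)
}

#' @describeIn ttaaIndex chromosome lengths of an index.
#' @param x,chromosome a [TTAAIndex-class] and a chromosome name.
#' @export
setMethod("seqlengths", "TTAAIndex", function(x) x@seqlengths)

#' TTAA positions on one chromosome
#'
#' @param x a [TTAAIndex-class].
#' @param chromosome chromosome name; `NULL` returns the full per-chromosome
#'   list.
#' @return integer vector of sorted 0-based TTAA start positions.
#' @export
ttaaSites <- function(x, chromosome = NULL) {
    stopifnot(is(x, "TTAAIndex"))
    if (is.null(chromosome)) return(x@sites)
    x@sites[[chromosome]]
}

#' Count TTAA sites in a genomic interval
#'
#' Number of TTAA start positions p with `start <= p < end` (0-based,
#' half-open). An unknown chromosome yields 0 with a warning rather than an
#' error, so genome/annotation naming mismatches stay visible but not fatal.
#'
#' @param index a [TTAAIndex-class].
#' @param chromosome chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return integer count.
#' @export
countTTAA <- function(index, chromosome, start, end) {
    stopifnot(is(index, "TTAAIndex"))
    if (any(start > end)) stop("'start' must be <= 'end'")
    sites <- index@sites[[chromosome]]
    if (is.null(sites)) {
        warning(sprintf("chromosome '%s' not in TTAAIndex; returning 0",
                        chromosome))
        return(rep.int(0L, length(start)))
    }
    ## sites < end minus sites < start, on the sorted site vector
    as.integer(findInterval(end - 0.5, sites) -
               findInterval(start - 0.5, sites))
}

#' Export TTAA sites as BED3
#'
#' Writes one 4 bp interval per TTAA site, BED convention.
#'
#' @param index a [TTAAIndex-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportTTAA <- function(index, path) {
    tabs <- lapply(names(index@sites), function(chrom) {
        p <- index@sites[[chrom]]
        if (!length(p)) return(NULL)
        data.frame(chrom = chrom, start = p, end = p + 4L)
    })
    tab <- do.call(rbind, tabs)
    if (is.null(tab))
        tab <- data.frame(chrom = character(), start = integer(),
                          end = integer())
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' Returns gene spans as a [GenomicRanges::GRanges] with a `gene_id`
#' metadata column. BED input uses the name field as `gene_id`. GFF3 input
#' keeps features of the given type (default `"gene"`) and takes `gene_id`
#' from the given attribute key (default `"ID"`).
#'
#' @param path BED or GFF3 file; format guessed from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff3"`.
#' @param featureType GFF3 feature type to keep.
#' @param idAttribute GFF3 attribute holding the gene identifier.
#' @return [GenomicRanges::GRanges] with `gene_id`.
#' @export
readGeneModels <- function(path, format = c("auto", "bed", "gff3"),
                           featureType = "gene", idAttribute = "ID") {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
            "gff3" else "bed"
    gr <- rtracklayer::import(path, format = format)
    if (format == "gff3") {
        gr <- gr[mcols(gr)$type == featureType]
        ids <- mcols(gr)[[idAttribute]]
        if (is.null(ids))
            stop(sprintf("GFF3 attribute '%s' not found", idAttribute))
    } else {
        ids <- mcols(gr)$name
        if (is.null(ids))
            stop("BED input must have a name column (BED6) for gene ids")
    }
    out <- granges(gr)
    mcols(out)$gene_id <- as.character(ids)
    if (any(!as.character(strand(out)) %in% c("+", "-")))
        stop("gene strand must be '+' or '-'")
    out
}

#' Strand-aware transcription start sites of gene models
#'
#' The TSS of a gene on the + strand is its leftmost base; on the - strand
#' its rightmost base. Returned in 0-based coordinates, matching the BED
#' convention used throughout.
#'
#' @param genes [GenomicRanges::GRanges] of gene spans with +/- strand.
#' @return integer vector of 0-based TSS positions, one per gene.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500),
#'                             strand = c("+"))
#' tssOf(g)  # 100
#' @export
tssOf <- function(genes) {
    stopifnot(is(genes, "GRanges"))
    st <- as.character(strand(genes))
    if (any(!st %in% c("+", "-")))
        stop("gene strand must be '+' or '-' to define a TSS")
    ifelse(st == "+", start(genes) - 1L, end(genes) - 1L)
}
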