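## deterministic synthetic calling-card experiments with ground truth:
## toy genome, gene models, background/foreground insertion libraries and
## a coupled differential-expression table.

#' Simulation parameters
#'
#' Defaults describe a desk-scale calling-card experiment: a 75 Mb genome
#' (5 chromosomes of 15 Mb) gives 5,000 hops the same one-hop-per-15-kb
#' density as a real library of ~200,000 insertions on a 3 Gb genome, so
#' hops stay sparse relative to the 5 kb clustering gap; 50 bound loci of
#' 500 bp placed within 500 bp of distinct TSSs receive, at
#' `backgroundMixture` 0.5, about 50 hops each — a strong local
#' enrichment over the ~0.017 background hops per TTAA.
#'
#' @param nChroms,chromLength chromosomes and their length in bp.
#' @param nGenes,geneLength non-overlapping gene models and their span.
#' @param nBoundLoci number of truly bound loci, one per (distinct) gene.
#' @param boundLocusWidth width of each bound locus in bp.
#' @param tssOffsetMax bound-locus centers are placed within this distance
#'   of a TSS (bp); mirrors binding concentrated near promoters.
#' @param placement `"tss"` (default) or `"random"` — the negative-control
#'   mode in which loci are placed uniformly over the genome.
#' @param nFgHops,nBgHops deduplicated hops in the foreground and
#'   background libraries.
#' @param backgroundMixture fraction of foreground hops drawn from the
#'   background (uniform-over-TTAA) distribution; the remainder
#'   concentrates at bound loci.
#' @param nBarcodes barcoded donors; 40 reflects four sets of ten donor
#'   plasmids. An independent event is a unique (position, strand,
#'   barcode), so the barcode count bounds how many events a narrow locus
#'   can host.
#' @param readLambda mean extra reads per hop (reads = 1 + Poisson).
#' @param deEffectMu,deSigma mean and sd of |log2 fold change| for truly
#'   responsive bound genes.
#' @param responsiveFraction probability a bound gene truly responds to
#'   depletion of the fused factor.
#' @param nullSigma sd of the null log2 fold changes.
#' @return a validated list of class `SimParams`.
#' @export
simParams <- function(nChroms = 5L, chromLength = 1.5e7, nGenes = 500L,
                      geneLength = 2000L, nBoundLoci = 50L,
                      boundLocusWidth = 500L, tssOffsetMax = 500L,
                      placement = c("tss", "random"),
                      nFgHops = 5000L, nBgHops = 5000L,
                      backgroundMixture = 0.5, nBarcodes = 40L,
                      readLambda = 3,
                      deEffectMu = 1.5, deSigma = 0.4,
                      responsiveFraction = 0.7, nullSigma = 0.2) {
    placement <- match.arg(placement)
    stopifnot(nChroms >= 1, chromLength >= 1000, nGenes >= 1,
              geneLength >= 1, nBoundLoci >= 1, nBoundLoci <= nGenes,
              boundLocusWidth >= 8, tssOffsetMax >= 0,
              nFgHops >= 1, nBgHops >= 1,
              backgroundMixture >= 0, backgroundMixture <= 1,
              nBarcodes >= 1, readLambda >= 0, deEffectMu >= 0,
              deSigma >= 0, responsiveFraction >= 0,
              responsiveFraction <= 1, nullSigma >= 0)
    structure(list(nChroms = as.integer(nChroms),
                   chromLength = as.integer(chromLength),
                   nGenes = as.integer(nGenes),
                   geneLength = as.integer(geneLength),
                   nBoundLoci = as.integer(nBoundLoci),
                   boundLocusWidth = as.integer(boundLocusWidth),
                   tssOffsetMax = as.integer(tssOffsetMax),
                   placement = placement,
                   nFgHops = as.integer(nFgHops),
                   nBgHops = as.integer(nBgHops),
                   backgroundMixture = backgroundMixture,
                   nBarcodes = as.integer(nBarcodes),
                   readLambda = readLambda,
                   deEffectMu = deEffectMu, deSigma = deSigma,
                   responsiveFraction = responsiveFraction,
                   nullSigma = nullSigma),
              class = "SimParams")
}

#' Generate a toy genome with gene models and TTAA index
#'
#' Chromosomes are i.i.d. uniform A/C/G/T (so TTAA density is ~1/256 per
#' bp); gene spans are placed uniformly without overlap, with uniform
#' strands. A pure function of (params, seed): the same seed reproduces
#' the genome byte for byte.
#'
#' @param params a [simParams()] list.
#' @param seed integer seed.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   ([GenomicRanges::GRanges] with `gene_id`), `ttaa`
#'   ([TTAAIndex-class]).
#' @export
generateGenome <- function(params = simParams(), seed = 1L) {
    stopifnot(inherits(params, "SimParams"))
    chromNames <- sprintf("chr%d", seq_len(params$nChroms))
    lens <- stats::setNames(rep(params$chromLength, params$nChroms),
                            chromNames)
    res <- withr::with_seed(seed, {
        seqs <- DNAStringSet(vapply(chromNames, function(nm)
            paste(sample(c("A", "C", "G", "T"), params$chromLength,
                         replace = TRUE), collapse = ""), character(1)))
        names(seqs) <- chromNames
        ## non-overlapping gene placement by iterated rejection
        n <- params$nGenes
        gl <- params$geneLength
        if (as.numeric(n) * gl > 0.5 * sum(as.numeric(lens)))
            stop("genes cannot be placed without overlap; ",
                 "use a larger genome or fewer/shorter genes")
        chrom <- character(0); st <- integer(0)
        for (round in seq_len(200L)) {
            need <- n - length(st)
            if (!need) break
            c2 <- sample(chromNames, need, replace = TRUE,
                         prob = as.numeric(lens))
            s2 <- floor(runif(need) * (lens[c2] - gl))
            chrom <- c(chrom, c2); st <- c(st, as.integer(s2))
            ord <- order(chrom, st)
            chrom <- chrom[ord]; st <- st[ord]
            keep <- rep(TRUE, length(st))
            lastEnd <- -1; lastChrom <- ""
            for (i in seq_along(st)) {
                if (chrom[i] == lastChrom && st[i] < lastEnd) {
                    keep[i] <- FALSE
                } else {
                    lastEnd <- st[i] + gl; lastChrom <- chrom[i]
                }
            }
            chrom <- chrom[keep]; st <- st[keep]
        }
        if (length(st) < n)
            stop("genes cannot be placed without overlap; ",
                 "use a larger genome or fewer/shorter genes")
        strand <- sample(c("+", "-"), n, replace = TRUE)
        list(seqs = seqs, chrom = chrom, st = st, strand = strand)
    })
    genes <- GRanges(res$chrom,
                     IRanges(res$st + 1L, width = params$geneLength),
                     strand = res$strand)
    seqlengths(genes) <- lens
    mcols(genes)$gene_id <- sprintf("G%04d", seq_len(params$nGenes))
    list(genome = res$seqs, genes = genes, ttaa = ttaaIndex(res$seqs))
}

#' Place bound loci and draw per-gene expression truth
#'
#' Each bound locus belongs to one distinct gene. In `"tss"` placement the
#' locus center falls within `tssOffsetMax` of that gene's TSS; in
#' `"random"` placement loci are uniform over the genome and the owning
#' gene is the nearest gene. Loci without a TTAA site are re-sited with a
#' warning (no insertions could land there). Each bound gene is truly
#' responsive with probability `responsiveFraction`; responsive genes get
#' a true log2 fold change of random sign and magnitude Normal(deEffectMu,
#' deSigma).
#'
#' @param genomeData output of [generateGenome()].
#' @param params a [simParams()] list.
#' @param seed integer seed.
#' @return a `SimTruth` list: `loci` (GRanges with `gene_id`),
#'   `boundGenes`, and `geneTable` (`gene_id`, `bound`, `isDE`,
#'   `trueLogFC` for every gene).
#' @export
simulateTruth <- function(genomeData, params = simParams(), seed = 1L) {
    stopifnot(inherits(params, "SimParams"))
    genes <- genomeData$genes
    index <- genomeData$ttaa
    lens <- seqlengths(index)
    w <- params$boundLocusWidth
    res <- withr::with_seed(seed, {
        pick <- sort(sample(length(genes), params$nBoundLoci))
        unused <- setdiff(seq_along(genes), pick)
        lchrom <- character(params$nBoundLoci)
        lstart <- integer(params$nBoundLoci)
        resited <- 0L
        for (i in seq_len(params$nBoundLoci)) {
            ok <- FALSE
            for (attempt in seq_len(50L)) {
                if (params$placement == "tss") {
                    g <- pick[i]
                    chrom <- as.character(seqnames(genes)[g])
                    anchor <- tssOf(genes[g])
                } else {
                    chrom <- sample(names(lens), 1L,
                                    prob = as.numeric(lens))
                    anchor <- floor(runif(1) * lens[[chrom]])
                }
                for (try in seq_len(20L)) {
                    center <- anchor +
                        round(runif(1, -params$tssOffsetMax,
                                    params$tssOffsetMax))
                    s <- max(0L, min(as.integer(center - w %/% 2),
                                     lens[[chrom]] - w))
                    if (countTTAA(index, chrom, s, s + w) > 0L) {
                        ok <- TRUE; break
                    }
                    resited <- resited + 1L
                }
                if (ok) break
                ## TTAA desert around this anchor: re-site to a fresh
                ## gene (tss placement) or a fresh position (random)
                if (params$placement == "tss") {
                    if (!length(unused))
                        stop("could not place a bound locus on a TTAA ",
                             "site: no genes left to re-site to")
                    repl <- sample(length(unused), 1L)
                    pick[i] <- unused[repl]
                    unused <- unused[-repl]
                }
            }
            if (!ok) stop("could not place a bound locus on a TTAA site")
            lchrom[i] <- chrom; lstart[i] <- s
        }
        isDE <- runif(params$nBoundLoci) < params$responsiveFraction
        lfc <- ifelse(isDE,
                      sample(c(-1, 1), params$nBoundLoci, replace = TRUE) *
                          rnorm(params$nBoundLoci, params$deEffectMu,
                                params$deSigma),
                      0)
        list(pick = pick, chrom = lchrom, start = lstart, isDE = isDE,
             lfc = lfc, resited = resited)
    })
    if (res$resited > 0L)
        warning(sprintf("%d bound-locus draw(s) re-sited (no TTAA site)",
                        res$resited))
    loci <- GRanges(res$chrom, IRanges(res$start + 1L, width = w))
    seqlengths(loci) <- lens[seqlevels(loci)]
    if (params$placement == "tss") {
        boundGenes <- mcols(genes)$gene_id[res$pick]
    } else {
        boundGenes <- nearestFeature(loci, genes)$gene_id
    }
    mcols(loci)$gene_id <- boundGenes
    geneTable <- data.frame(gene_id = mcols(genes)$gene_id,
                            bound = FALSE, isDE = FALSE, trueLogFC = 0)
    m <- match(boundGenes, geneTable$gene_id)
    geneTable$bound[m] <- TRUE
    geneTable$isDE[m] <- res$isDE
    geneTable$trueLogFC[m] <- res$lfc
    structure(list(loci = loci, boundGenes = boundGenes,
                   geneTable = geneTable, placement = params$placement),
              class = "SimTruth")
}

## decode a combo id into (site index within pool, strand, barcode)
.decodeCombo <- function(id, nStrand = 2L, nBarcode) {
    id0 <- id - 1
    list(site = id0 %/% (nStrand * nBarcode) + 1L,
         strand = c("+", "-")[(id0 %/% nBarcode) %% nStrand + 1L],
         barcode = id0 %% nBarcode + 1L)
}

#' Simulate foreground and background insertion libraries
#'
#' Background hops are uniform over all TTAA sites of the genome; each
#' foreground hop comes from the background distribution with probability
#' `backgroundMixture` and otherwise from a uniformly chosen bound locus
#' (uniform over that locus's TTAA sites). Strand and barcode are uniform.
#' A hop is a unique (chromosome, position, strand, barcode): collisions
#' are re-drawn, so the libraries contain exactly `nFgHops` and `nBgHops`
#' deduplicated hops. If a bound locus saturates (more draws than it has
#' distinct site/strand/barcode combinations) the excess spills into the
#' uniform component with a warning. A pure function of (inputs, seed).
#'
#' @param genomeData output of [generateGenome()].
#' @param truth output of [simulateTruth()].
#' @param params a [simParams()] list.
#' @param seed integer seed.
#' @param fgSample,bgSample sample labels.
#' @return list with `fg` and `bg` [InsertionSet-class]s, coordinate
#'   sorted.
#' @export
simulateInsertions <- function(genomeData, truth, params = simParams(),
                               seed = 1L, fgSample = "FG",
                               bgSample = "BG") {
    stopifnot(inherits(params, "SimParams"), inherits(truth, "SimTruth"))
    index <- genomeData$ttaa
    sites <- ttaaSites(index)
    chromOf <- rep(names(sites), lengths(sites))
    posOf <- unlist(sites, use.names = FALSE)
    nSites <- length(posOf)
    if (!nSites) stop("genome contains no TTAA sites")
    nBc <- params$nBarcodes
    loci <- truth$loci
    lociSiteIdx <- lapply(seq_along(loci), function(i) {
        chrom <- as.character(seqnames(loci)[i])
        which(chromOf == chrom & posOf >= start(loci)[i] - 1L &
              posOf < end(loci)[i])
    })

    drawUniform <- function(n, exclude) {
        ## unique (site, strand, barcode) keys not already in `exclude`
        keys <- character(0)
        while (length(keys) < n) {
            need <- n - length(keys)
            idx <- sample.int(nSites, need, replace = TRUE)
            k <- paste(idx, sample.int(2L, need, replace = TRUE),
                       sample.int(nBc, need, replace = TRUE))
            k <- setdiff(unique(k), c(exclude, keys))
            keys <- c(keys, k)
        }
        keys[seq_len(n)]
    }
    keyToRecord <- function(keys) {
        f <- matrix(as.integer(unlist(strsplit(keys, " ", fixed = TRUE))),
                    ncol = 3L, byrow = TRUE)
        data.frame(chrom = chromOf[f[, 1L]], pos = posOf[f[, 1L]],
                   strand = c("+", "-")[f[, 2L]], barcode = f[, 3L])
    }

    res <- withr::with_seed(seed, {
        bgKeys <- drawUniform(params$nBgHops, character(0))
        nBound <- sum(runif(params$nFgHops) >=
                      params$backgroundMixture)
        spill <- 0L
        boundKeys <- character(0)
        if (nBound > 0L) {
            lociDraw <- sample.int(length(loci), nBound, replace = TRUE)
            counts <- tabulate(lociDraw, nbins = length(loci))
            for (l in seq_along(loci)) {
                if (!counts[l]) next
                pool <- lociSiteIdx[[l]]
                cap <- length(pool) * 2L * nBc
                take <- min(counts[l], cap)
                spill <- spill + counts[l] - take
                combos <- sample.int(cap, take)
                dec <- .decodeCombo(combos, 2L, nBc)
                boundKeys <- c(boundKeys,
                               paste(pool[dec$site],
                                     match(dec$strand, c("+", "-")),
                                     dec$barcode))
            }
        }
        nUnif <- params$nFgHops - length(boundKeys)
        fgKeys <- c(boundKeys, drawUniform(nUnif, boundKeys))
        fgReads <- 1L + rpois(params$nFgHops, params$readLambda)
        bgReads <- 1L + rpois(params$nBgHops, params$readLambda)
        list(bgKeys = bgKeys, fgKeys = fgKeys, spill = spill,
             fgReads = fgReads, bgReads = bgReads)
    })
    if (res$spill > 0L)
        warning(sprintf(
            "%d bound-locus draw(s) exceeded locus capacity; spilled to background distribution",
            res$spill))
    fgRec <- keyToRecord(res$fgKeys)
    bgRec <- keyToRecord(res$bgKeys)
    fg <- InsertionSet(fgRec$chrom, fgRec$pos, fgRec$strand,
                       sprintf("BC%02d", fgRec$barcode), res$fgReads,
                       fgSample, seqlengths = seqlengths(index))
    bg <- InsertionSet(bgRec$chrom, bgRec$pos, bgRec$strand,
                       sprintf("BC%02d", bgRec$barcode), res$bgReads,
                       bgSample, seqlengths = seqlengths(index))
    list(fg = dedupHops(fg), bg = dedupHops(bg))
}

#' Simulate a gene-level differential-expression table
#'
#' Truly responsive bound genes keep their true log2 fold change and get
#' an adjusted p drawn Uniform(0, 0.01]; every other gene is null: log2FC
#' ~ Normal(0, nullSigma) and adjusted p Uniform(0.01, 1]. A pure function
#' of (truth, seed).
#'
#' @param truth output of [simulateTruth()].
#' @param geneIds all gene ids to report (default: every gene in truth).
#' @param params a [simParams()] list.
#' @param seed integer seed.
#' @return `data.frame(gene_id, logFC, pAdj)`.
#' @export
simulateExpression <- function(truth, geneIds = NULL,
                               params = simParams(), seed = 1L) {
    stopifnot(inherits(truth, "SimTruth"))
    gt <- truth$geneTable
    if (is.null(geneIds)) geneIds <- gt$gene_id
    m <- match(geneIds, gt$gene_id)
    de <- !is.na(m) & gt$isDE[m]
    n <- length(geneIds)
    withr::with_seed(seed, {
        logFC <- rnorm(n, 0, params$nullSigma)
        logFC[de] <- gt$trueLogFC[m[de]]
        pAdj <- runif(n, 0.01, 1)
        pAdj[de] <- runif(sum(de), 0, 0.01)
    })
    data.frame(gene_id = geneIds, logFC = logFC, pAdj = pAdj)
}

#' Simulate a complete calling-card experiment
#'
#' Convenience wrapper chaining [generateGenome()], [simulateTruth()],
#' [simulateInsertions()] and [simulateExpression()]. Stage seeds are
#' derived from `seed` (seed, seed+1, seed+2, seed+3) so every output is
#' a pure function of (params, seed).
#'
#' @param params a [simParams()] list.
#' @param seed integer seed.
#' @param genomeData optionally reuse an existing [generateGenome()]
#'   result (the genome is by far the most expensive stage).
#' @return list with `genome`, `genes`, `ttaa`, `truth`, `fg`, `bg`,
#'   `expression`, `params`, `seed`.
#' @export
simulateCallingCards <- function(params = simParams(), seed = 1L,
                                 genomeData = NULL) {
    if (is.null(genomeData))
        genomeData <- generateGenome(params, seed)
    truth <- simulateTruth(genomeData, params, seed + 1L)
    ins <- simulateInsertions(genomeData, truth, params, seed + 2L)
    expr <- simulateExpression(truth, NULL, params, seed + 3L)
    list(genome = genomeData$genome, genes = genomeData$genes,
         ttaa = genomeData$ttaa, truth = truth, fg = ins$fg, bg = ins$bg,
         expression = expr, params = params, seed = seed)
}

#' Compare called peaks against simulation truth
#'
#' A bound locus is recovered when at least one significant peak overlaps
#' it; a significant peak is a true positive when it overlaps a bound
#' locus. Gene assignment is correct for a recovered locus when some
#' overlapping significant peak is annotated to that locus's gene.
#'
#' @param peaks a [CalledPeaks-class] (annotated, if gene accuracy is
#'   wanted).
#' @param truth output of [simulateTruth()].
#' @return list with `recall`, `precision`, `geneAccuracy` (NA when peaks
#'   are unannotated), `nSignificant`, `nLoci`.
#' @export
evaluateRecovery <- function(peaks, truth) {
    stopifnot(is(peaks, "CalledPeaks"), inherits(truth, "SimTruth"))
    sig <- peaks[mcols(peaks)$significant]
    loci <- truth$loci
    hits <- findOverlaps(loci, sig, ignore.strand = TRUE)
    recovered <- unique(queryHits(hits))
    recall <- length(recovered) / length(loci)
    precision <- if (length(sig))
        length(unique(subjectHits(hits))) / length(sig) else NA_real_
    geneAccuracy <- NA_real_
    if (!is.null(mcols(sig)$nearestGene) && length(recovered)) {
        ok <- vapply(recovered, function(i) {
            pk <- subjectHits(hits)[queryHits(hits) == i]
            any(mcols(sig)$nearestGene[pk] == mcols(loci)$gene_id[i],
                na.rm = TRUE)
        }, logical(1))
        geneAccuracy <- mean(ok)
    }
    list(recall = recall, precision = precision,
         geneAccuracy = geneAccuracy, nSignificant = length(sig),
         nLoci = length(loci))
}

#' Write simulation truth as JSON
#'
#' @param truth output of [simulateTruth()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
    loci <- truth$loci
    jsonlite::write_json(list(
        placement = truth$placement,
        loci = data.frame(chrom = as.character(seqnames(loci)),
                          start = start(loci) - 1L, end = end(loci),
                          gene_id = mcols(loci)$gene_id),
        genes = truth$geneTable), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
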