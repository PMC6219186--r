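test_that("the generator is a pure function of (params, seed)", {
    p <- ccSmallParams()
    g1 <- generateGenome(p, seed = 3L)
    g2 <- generateGenome(p, seed = 3L)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_identical(GenomicRanges::start(g1$genes),
                     GenomicRanges::start(g2$genes))
    s1 <- suppressWarnings(simulateCallingCards(p, 5L, genomeData = g1))
    s2 <- suppressWarnings(simulateCallingCards(p, 5L, genomeData = g2))
    expect_identical(hopPositions(s1$fg), hopPositions(s2$fg))
    expect_identical(S4Vectors::mcols(s1$fg)$barcode,
                     S4Vectors::mcols(s2$fg)$barcode)
    expect_equal(s1$expression, s2$expression)
    s3 <- suppressWarnings(simulateCallingCards(p, 6L, genomeData = g1))
    expect_false(identical(hopPositions(s1$fg), hopPositions(s3$fg)))
})

test_that("generated genomes have disjoint genes and uniform TTAA density", {
    g <- ccSmallGenome()
    genes <- BiocGenerics::sort(g$genes, ignore.strand = TRUE)
    byChrom <- split(genes, GenomicRanges::seqnames(genes))
    for (gc in byChrom) {
        if (length(gc) < 2) next
        expect_true(all(GenomicRanges::start(gc)[-1] >
                        GenomicRanges::end(gc)[-length(gc)]))
    }
    len <- sum(as.numeric(GenomeInfoDb::seqlengths(g$ttaa)))
    nSites <- sum(lengths(ttaaSites(g$ttaa)))
    expected <- len / 256
    expect_lt(abs(nSites - expected), 4 * sqrt(expected))
})

test_that("insertion libraries have exact hop counts on TTAA sites", {
    g <- ccSmallGenome()
    p <- ccSmallParams()
    sim <- suppressWarnings(simulateCallingCards(p, 9L, genomeData = g))
    expect_identical(length(sim$fg), p$nFgHops)
    expect_identical(length(sim$bg), p$nBgHops)
    ## deduplication is a no-op: events are unique by construction
    expect_identical(length(dedupHops(sim$fg)), p$nFgHops)
    for (x in list(sim$fg, sim$bg)) {
        chrom <- as.character(GenomicRanges::seqnames(x))
        pos <- hopPositions(x)
        onSite <- vapply(unique(chrom), function(cc)
            all(pos[chrom == cc] %in% ttaaSites(g$ttaa, cc)), logical(1))
        expect_true(all(onSite))
        expect_true(all(S4Vectors::mcols(x)$barcode %in%
                        sprintf("BC%02d", seq_len(p$nBarcodes))))
    }
})

test_that("bound loci receive the expected share of foreground hops", {
    run <- ccDefaultRun()
    p <- run$params
    nBoundDraws <- sum(GenomicRanges::countOverlaps(
        run$fg, run$truth$loci, ignore.strand = TRUE) > 0)
    expected <- p$nFgHops * (1 - p$backgroundMixture)
    ## binomial component assignment plus a uniform-hop trickle into loci
    sd <- sqrt(p$nFgHops * p$backgroundMixture *
               (1 - p$backgroundMixture))
    expect_gt(nBoundDraws, expected - 4 * sd)
    expect_lt(nBoundDraws, expected + 4 * sd + 30)
    meanPerLocus <- expected / p$nBoundLoci
    expect_equal(meanPerLocus, 50)   # the designed study condition
})

test_that("bound loci sit near the TSS of their gene under tss placement", {
    run <- ccDefaultRun()
    loci <- run$truth$loci
    genes <- run$genes
    m <- match(S4Vectors::mcols(loci)$gene_id,
               S4Vectors::mcols(genes)$gene_id)
    tss <- tssOf(genes)[m]
    center <- (GenomicRanges::start(loci) - 1 +
               GenomicRanges::end(loci)) / 2
    ## center within tssOffsetMax of the TSS, allowing for clipping and
    ## the half-locus rounding
    expect_true(all(abs(center - tss) <=
                    run$params$tssOffsetMax + run$params$boundLocusWidth))
    expect_identical(length(unique(S4Vectors::mcols(loci)$gene_id)),
                     run$params$nBoundLoci)
})

test_that("expression truth follows the responsive-fraction model", {
    g <- generateGenome(simParams(nChroms = 2L, chromLength = 2e6,
                                  nGenes = 300L, nBoundLoci = 250L),
                        seed = 30L)
    pAll <- simParams(nChroms = 2L, chromLength = 2e6, nGenes = 300L,
                      nBoundLoci = 250L, responsiveFraction = 1)
    tAll <- suppressWarnings(simulateTruth(g, pAll, 31L))
    eAll <- simulateExpression(tAll, params = pAll, seed = 32L)
    bound <- tAll$geneTable$bound
    expect_true(all(eAll$pAdj[bound] <= 0.01))
    expect_true(all(eAll$pAdj[!bound] > 0.01))

    pNone <- simParams(nChroms = 2L, chromLength = 2e6, nGenes = 300L,
                       nBoundLoci = 250L, responsiveFraction = 0)
    tNone <- suppressWarnings(simulateTruth(g, pNone, 33L))
    eNone <- simulateExpression(tNone, params = pNone, seed = 34L)
    expect_true(all(eNone$pAdj > 0.01))

    p7 <- simParams(nChroms = 2L, chromLength = 2e6, nGenes = 300L,
                    nBoundLoci = 250L)
    t7 <- suppressWarnings(simulateTruth(g, p7, 35L))
    nResp <- sum(t7$geneTable$isDE)
    expect_lt(abs(nResp - 250 * 0.7), 4 * sqrt(250 * 0.7 * 0.3))
    ## |log2FC| > 1 among true responders matches the normal tail
    lfc <- t7$geneTable$trueLogFC[t7$geneTable$isDE]
    pTail <- pnorm((1.5 - 1) / 0.4)
    expect_lt(abs(mean(abs(lfc) > 1) - pTail), 0.05 + 3 * sqrt(
        pTail * (1 - pTail) / length(lfc)))
})

test_that("truth JSON round-trips", {
    g <- ccSmallGenome()
    t1 <- suppressWarnings(simulateTruth(g, ccSmallParams(), 44L))
    f <- withr::local_tempfile(fileext = ".json")
    writeTruth(t1, f)
    t2 <- readTruth(f)
    expect_identical(GenomicRanges::start(t2$loci),
                     GenomicRanges::start(t1$loci))
    expect_identical(S4Vectors::mcols(t2$loci)$gene_id,
                     S4Vectors::mcols(t1$loci)$gene_id)
    expect_equal(t2$geneTable$trueLogFC, t1$geneTable$trueLogFC)
})
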