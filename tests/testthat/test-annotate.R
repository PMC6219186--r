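mkGenes <- function(chrom, start0, end0, id, strand = "+") {
    g <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(start0 + 1L, end0),
                                strand = strand)
    S4Vectors::mcols(g)$gene_id <- id
    g
}

test_that("nearestFeature implements closest-interval semantics with tie-breaks", {
    genes <- mkGenes(c("chr1", "chr1"), c(2000L, 10000L),
                     c(3000L, 11000L), c("A", "B"))
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
    nf <- nearestFeature(pk, genes)
    expect_identical(nf$gene_id, "A")
    expect_identical(nf$distance, 900L)
    ## overlap -> distance 0
    pk2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, 2600))
    expect_identical(nearestFeature(pk2, genes)$distance, 0L)
    ## equidistant tie -> smaller gene start
    genes3 <- mkGenes(c("chr1", "chr1"), c(500L, 1200L), c(900L, 1600L),
                      c("Z", "Y"))
    pk3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
    expect_identical(nearestFeature(pk3, genes3)$gene_id, "Z")
    ## same start -> lexicographic id
    genes4 <- mkGenes(c("chr1", "chr1"), c(500L, 500L), c(900L, 900L),
                      c("beta", "alpha"))
    expect_identical(nearestFeature(pk3, genes4)$gene_id, "alpha")
    ## chromosome without genes -> NA with warning
    pk4 <- GenomicRanges::GRanges(factor("chrM", c("chrM", "chr1")),
                                  IRanges::IRanges(1, 100))
    expect_warning(nf4 <- nearestFeature(pk4, genes), "without genes")
    expect_true(is.na(nf4$gene_id))
})

test_that("nearestFeature agrees with the all-pairs brute force", {
    set.seed(31)
    gChrom <- sample(c("chr1", "chr2"), 40, TRUE)
    gStart <- sample.int(1e5, 40) - 1L
    gEnd <- gStart + sample(100:5000, 40, TRUE)
    gId <- sprintf("g%02d", sample.int(99, 40))
    genes <- mkGenes(gChrom, gStart, gEnd, gId)
    pChrom <- sample(c("chr1", "chr2"), 200, TRUE)
    pStart <- sample.int(1.2e5, 200) - 1L
    pEnd <- pStart + sample(4:2000, 200, TRUE)
    pk <- GenomicRanges::GRanges(pChrom,
                                 IRanges::IRanges(pStart + 1L, pEnd))
    got <- nearestFeature(pk, genes)
    want <- naiveNearest(pChrom, pStart, pEnd, gChrom, gStart, gEnd, gId)
    expect_identical(got$gene_id, want[, 1L])
    expect_identical(got$distance, as.integer(want[, 2L]))
})

test_that("tssDistances measures from the peak midpoint to the nearest TSS", {
    genes <- mkGenes("chr1", 100L, 500L, "A")          # TSS 100
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 110))
    expect_identical(tssDistances(pk, genes), 0)       # midpoint 100
    genes2 <- mkGenes(c("chr1", "chr1"), c(1000L, 5000L),
                      c(2000L, 6000L), c("A", "B"))
    pk2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 8))
    expect_identical(tssDistances(pk2, genes2), 996)   # midpoint 4
    ## minus-strand TSS sits at the right edge
    genes3 <- mkGenes("chr1", 1000L, 2000L, "A", strand = "-")
    expect_identical(tssDistances(pk2, genes3), 1999 - 4)
    expect_identical(tssDistances(pk2, genes3, signed = TRUE), 4 - 1999)
})

test_that("tssDistances agrees with the exhaustive oracle", {
    set.seed(13)
    for (i in 1:30) {
        nG <- sample(1:30, 1)
        genes <- mkGenes(sample(c("chr1", "chr2"), nG, TRUE),
                         st <- sample.int(1e5, nG) - 1L,
                         st + 1000L, sprintf("g%d", seq_len(nG)),
                         strand = sample(c("+", "-"), nG, TRUE))
        pChrom <- sample(c("chr1", "chr2"), 50, TRUE)
        pStart <- sample.int(1e5, 50) - 1L
        pk <- GenomicRanges::GRanges(pChrom,
                                     IRanges::IRanges(pStart + 1L,
                                                      pStart + 200L))
        got <- suppressWarnings(tssDistances(pk, genes))
        tss <- tssOf(genes)
        gch <- as.character(GenomicRanges::seqnames(genes))
        mid <- floor((pStart + pStart + 200) / 2)
        want <- vapply(seq_len(50), function(j) {
            d <- abs(mid[j] - tss[gch == pChrom[j]])
            if (length(d)) min(d) else NA_real_
        }, numeric(1))
        expect_equal(got, want)
    }
})

test_that("mannWhitneyU: exact small-sample enumeration", {
    r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$U, 0)
    expect_equal(r$pValue, 0.1)          # 2 x 1/20 arrangements
    expect_match(r$method, "exact")
    r1 <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "less")
    expect_equal(r1$pValue, 0.05)
    ## identical multisets show no separation
    expect_gte(mannWhitneyU(c(1, 2, 2, 3), c(1, 2, 2, 3))$pValue, 0.99)
    ## U bounds
    expect_true(r$U >= 0 && r$U <= r$n1 * r$n2)
    expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("mannWhitneyU exact enumeration matches wilcox.test on untied data", {
    set.seed(17)
    for (i in 1:25) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        x <- sample.int(1000, n1 + n2)   # untied
        a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
        got <- mannWhitneyU(a, b)
        want <- wilcox.test(a, b, exact = TRUE)
        expect_equal(got$U, unname(want$statistic))
        expect_equal(got$pValue, want$p.value, tolerance = 1e-12)
    }
})

test_that("mannWhitneyU large-sample approximation matches the reference formula", {
    set.seed(23)
    for (i in 1:10) {
        a <- rnorm(100); b <- rnorm(100, 0.3)
        got <- mannWhitneyU(a, b)
        want <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
        expect_equal(got$pValue, want$p.value, tolerance = 1e-6)
        gl <- mannWhitneyU(a, b, "less")
        wl <- wilcox.test(a, b, alternative = "less", exact = FALSE,
                          correct = TRUE)
        expect_equal(gl$pValue, wl$p.value, tolerance = 1e-6)
    }
    ## heavy ties engage the tie correction
    a <- sample(1:4, 60, TRUE); b <- sample(1:4, 50, TRUE)
    expect_equal(mannWhitneyU(a, b)$pValue,
                 wilcox.test(a, b, exact = FALSE)$p.value,
                 tolerance = 1e-6)
})

test_that("randomPositions is deterministic, in-bounds, length-proportional", {
    lens <- c(chrA = 3e6, chrB = 1e6)
    g1 <- randomPositions(lens, 500, seed = 4L)
    g2 <- randomPositions(lens, 500, seed = 4L)
    expect_identical(GenomicRanges::start(g1), GenomicRanges::start(g2))
    expect_true(all(GenomicRanges::start(g1) >= 1))
    ok <- GenomicRanges::start(g1) <=
        lens[as.character(GenomicRanges::seqnames(g1))]
    expect_true(all(ok))
    ## 3:1 chromosome usage within 4 binomial SD
    g3 <- randomPositions(lens, 10000, seed = 5L)
    nA <- sum(as.character(GenomicRanges::seqnames(g3)) == "chrA")
    expect_lt(abs(nA - 7500), 4 * sqrt(10000 * 0.75 * 0.25))
    expect_identical(S4Vectors::metadata(g3)$seed, 5L)
})

test_that("interval and gene-set Venn summaries are exact", {
    a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
    b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15))
    v <- intervalOverlapVenn(a, b)
    expect_identical(v$sharedA, 1L)
    expect_identical(v$sharedB, 1L)
    d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 110))
    v2 <- intervalOverlapVenn(a, d)
    expect_identical(unlist(v2[c("onlyA", "sharedA", "onlyB")]),
                     c(onlyA = 1L, sharedA = 0L, onlyB = 1L))
    ## random sets vs quadratic brute force
    set.seed(41)
    for (i in 1:20) {
        sa <- sample.int(5000, 30); sb <- sample.int(5000, 25)
        ga <- GenomicRanges::GRanges("c", IRanges::IRanges(sa, sa + 99))
        gb <- GenomicRanges::GRanges("c", IRanges::IRanges(sb, sb + 99))
        v <- intervalOverlapVenn(ga, gb)
        brute <- outer(seq_along(ga), seq_along(gb), function(i, j)
            sa[i] <= sb[j] + 99 & sb[j] <= sa[i] + 99)
        expect_identical(v$sharedA, sum(rowSums(brute) > 0))
        expect_identical(v$sharedB, sum(colSums(brute) > 0))
        expect_identical(v$sharedPairs, sum(brute))
    }
    gv <- geneSetVenn(c("X", "Y"), c("Y", "Z"))
    expect_identical(gv$counts, c(onlyA = 1L, shared = 1L, onlyB = 1L))
    expect_setequal(gv$union, c("X", "Y", "Z"))
    gv2 <- geneSetVenn(c("A", "B"), c("B", "A"))
    expect_identical(gv2$counts[["shared"]], 2L)
})

test_that("tssDistanceHistogram bins symmetric and one-sided ranges", {
    h <- tssDistanceHistogram(c(0, 100, 499, 500, 2000), binWidth = 500,
                              range = 2500)
    expect_identical(h$count[h$bin_start == 0], 3L)
    expect_identical(h$count[h$bin_start == 500], 1L)
    expect_identical(sum(h$count), 5L)
    hs <- tssDistanceHistogram(c(-700, -100, 100), binWidth = 500,
                               range = 1000)
    expect_identical(hs$count[hs$bin_start == -1000], 1L)
    expect_identical(hs$count[hs$bin_start == -500], 1L)
    expect_identical(hs$count[hs$bin_start == 0], 1L)
})
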