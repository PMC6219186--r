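test_that("clusterInsertions applies the maximum-gap rule", {
    expect_identical(clusterInsertions(100), list(100))
    ## 2900 <= 5000 joins; 6000 > 5000 splits
    expect_identical(clusterInsertions(c(100, 3000, 9000), 5000),
                     list(c(100, 3000), 9000))
    expect_error(clusterInsertions(c(5, 1)), "sorted")
    ## duplicated positions stay in one cluster
    expect_identical(clusterInsertions(c(7, 7, 7), 0), list(c(7, 7, 7)))
})

test_that("clusterInsertions equals the union-find transitive closure", {
    set.seed(5)
    for (i in 1:100) {
        n <- sample(2:50, 1)
        pos <- sort(sample.int(2e5, n, replace = TRUE))
        gap <- sample(c(0, 10, 500, 5000, 20000), 1)
        got <- clusterInsertions(pos, gap)
        want <- naiveCluster(pos, gap)
        expect_identical(unname(got), unname(want))
    }
})

test_that("peakSpan covers the final tetranucleotide", {
    expect_identical(peakSpan(100), c(100, 104))
    expect_identical(peakSpan(c(100, 3000)), c(100, 3004))
    expect_error(peakSpan(numeric(0)), "empty")
    set.seed(2)
    g <- sort(sample.int(1e5, 17))
    sp <- peakSpan(g)
    expect_gte(sp[2] - sp[1], 4)
})

test_that("estimateLambda takes the maximum rate over three nested windows", {
    ## peak [10000, 10504): 2 TTAA under the peak, 8 within +-1 kb,
    ## 50 within +-5 kb; background hops 0 / 4 / 10 in the same windows
    sites <- sort(c(10100L, 10300L,
                    9100L, 9200L, 9300L, 11000L, 11100L, 11200L,
                    5000L + 0:20 * 190L, 11600L + 0:20 * 190L))
    idx <- new("TTAAIndex", sites = list(chr1 = sites),
               seqlengths = c(chr1 = 30000L))
    bg <- sort(c(9500, 9600, 10900, 11010,
                 6000, 6100, 6200, 13000, 13100, 13200))
    expect_identical(countTTAA(idx, "chr1", 10000, 10504), 2L)
    expect_identical(countTTAA(idx, "chr1", 9000, 11504), 8L)
    expect_identical(countTTAA(idx, "chr1", 5000, 15504), 50L)
    lam <- estimateLambda("chr1", 10000, 10504, bg, idx)
    ## rates: max(0,1)/2, max(4,1)/8, max(10,1)/50 -> max 0.5; x 2 TTAA
    expect_equal(lam, 1.0)
    ## depth scaling is linear
    expect_equal(estimateLambda("chr1", 10000, 10504, bg, idx,
                                depthRatio = 2), 2 * lam)
})

test_that("estimateLambda floors empty backgrounds and skips TTAA-free windows", {
    ## all 10 TTAA sit under the peak; no background hops anywhere
    idx <- new("TTAAIndex", sites = list(chr1 = 10000L + 0:9 * 50L),
               seqlengths = c(chr1 = 30000L))
    lam <- estimateLambda("chr1", 10000, 10454, numeric(0), idx)
    expect_equal(lam, 1 / 10 * 10)
    ## no TTAA in any window: lambda falls back to the floor
    idx0 <- new("TTAAIndex", sites = list(chr1 = integer(0)),
                seqlengths = c(chr1 = 30000L))
    expect_equal(estimateLambda("chr1", 10000, 10504, numeric(0), idx0),
                 1)
    expect_equal(estimateLambda("chr1", 10000, 10504, numeric(0), idx0,
                                depthRatio = 0.5), 0.5)
})

test_that("poissonUpperTail matches pmf summation and is monotone", {
    expect_equal(poissonUpperTail(0, 3.7), 1.0)
    expect_equal(poissonUpperTail(5, 1), 1 - sum(exp(-1) / factorial(0:4)),
                 tolerance = 1e-12)
    expect_equal(poissonUpperTail(2, 2), 1 - exp(-2) * 3, tolerance = 1e-12)
    for (lambda in c(0.01, 0.1, 1, 5, 20, 50))
        for (k in c(0L, 1L, 2L, 5L, 10L, 50L, 100L, 200L))
            expect_lt(abs(poissonUpperTail(k, lambda) -
                          naivePoissonTail(k, lambda)), 1e-9)
    ## non-increasing in k, non-decreasing in lambda
    p <- poissonUpperTail(0:30, 4)
    expect_true(all(diff(p) <= 0))
    p <- poissonUpperTail(6, c(0.5, 1, 2, 4, 8))
    expect_true(all(diff(p) >= 0))
    expect_error(poissonUpperTail(-1, 1), "k")
    expect_error(poissonUpperTail(1, -2), "lambda")
})

test_that("bhAdjust is the Benjamini-Hochberg step-up", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    set.seed(8)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        q <- bhAdjust(p)
        expect_equal(q, naiveBH(p), tolerance = 1e-12)
        expect_true(all(q >= p - 1e-15))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hopCountHistogram tallies hops per locus exactly", {
    expect_identical(hopCountHistogram(c(2L, 2L, 5L)),
                     data.frame(hops = c(2L, 5L), loci = c(2L, 1L)))
    expect_identical(nrow(hopCountHistogram(integer(0))), 0L)
    set.seed(3)
    x <- sample(1:20, 300, TRUE)
    h <- hopCountHistogram(x)
    expect_identical(sum(h$loci), 300L)
    for (i in seq_len(nrow(h)))
        expect_identical(h$loci[i], sum(x == h$hops[i]))
})

test_that("callPeaks honors its structural contract on simulated data", {
    g <- ccSmallGenome()
    sim <- suppressWarnings(simulateCallingCards(
        ccSmallParams(), seed = 21L, genomeData = g))
    pk <- callPeaks(sim$fg, sim$bg, sim$ttaa)
    md <- S4Vectors::mcols(pk)
    expect_s4_class(pk, "CalledPeaks")
    expect_true(all(md$pValue >= 0 & md$pValue <= 1))
    expect_true(all(md$qValue[md$candidate] >=
                    md$pValue[md$candidate] - 1e-12))
    expect_true(all(is.na(md$qValue[!md$candidate])))
    expect_true(all(!md$significant[!md$candidate]))
    expect_true(all(md$hops[md$candidate] >= 2L))
    ## sorted by (chromosome, start)
    expect_false(is.unsorted(order(as.character(
        GenomicRanges::seqnames(pk)), GenomicRanges::start(pk))))
    ## every foreground hop falls inside exactly one cluster span
    ov <- GenomicRanges::countOverlaps(sim$fg, pk, type = "within",
                                       ignore.strand = TRUE)
    expect_true(all(ov == 1L))
    ## hop totals across clusters conserve the library
    expect_identical(sum(md$hops), length(sim$fg))
})

test_that("callPeaks requires a background and tolerates an empty foreground", {
    g <- ccSmallGenome()
    sim <- suppressWarnings(simulateCallingCards(
        ccSmallParams(), seed = 22L, genomeData = g))
    emptySet <- InsertionSet()
    expect_error(callPeaks(sim$fg, emptySet, sim$ttaa), "background")
    expect_length(callPeaks(emptySet, sim$bg, sim$ttaa), 0)
})
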