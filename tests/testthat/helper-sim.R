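## shared fixtures, built once per test run and memoized: the default
## synthetic genome is the expensive piece (~50 Mb of sequence).

.ccCache <- new.env(parent = emptyenv())

ccMemo <- function(key, expr) {
    if (!exists(key, envir = .ccCache))
        assign(key, expr, envir = .ccCache)
    get(key, envir = .ccCache)
}

## default study-condition genome (5 x 15 Mb, 500 genes)
ccDefaultGenome <- function() {
    ccMemo("defaultGenome", generateGenome(simParams(), seed = 1L))
}

## full default experiment at seed 1 with called + annotated peaks
ccDefaultRun <- function() {
    ccMemo("defaultRun", {
        sim <- suppressWarnings(
            simulateCallingCards(simParams(), seed = 1L,
                                 genomeData = ccDefaultGenome()))
        peaks <- annotatePeaks(callPeaks(sim$fg, sim$bg, sim$ttaa),
                               sim$genes)
        c(sim, list(peaksAnnotated = peaks))
    })
}

## small genome for fast pipeline-level tests (4 Mb, 60 genes)
ccSmallParams <- function(chromLength = 2e6, ...) {
    simParams(nChroms = 2L, chromLength = chromLength, nGenes = 60L,
              nBoundLoci = 8L, nFgHops = 600L, nBgHops = 600L, ...)
}

ccSmallGenome <- function() {
    ccMemo("smallGenome", generateGenome(ccSmallParams(), seed = 11L))
}

## tiny deterministic insertion set for I/O tests
ccToyInsertions <- function() {
    InsertionSet(chromosome = c("chr1", "chr1", "chr2"),
                 pos = c(100L, 350L, 42L),
                 strand = c("+", "-", "+"),
                 barcode = c("BC01", "BC02", "BC01"),
                 reads = c(3L, 1L, 9L),
                 sampleID = "toy")
}
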