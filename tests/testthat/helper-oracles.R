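## brute-force oracles kept deliberately naive and independent of the
## package implementations they check.

## sliding-window 4-mer scan
naiveScanTTAA <- function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 4L) return(integer())
    hits <- vapply(seq_len(n - 3L), function(i)
        substr(s, i, i + 3L) == "TTAA", logical(1))
    which(hits) - 1L
}

## linear scan count of sites in [start, end)
naiveCountTTAA <- function(sites, start, end) sum(sites >= start & sites < end)

## transitive closure of the "gap <= maxGap" relation via union-find
naiveCluster <- function(pos, maxGap) {
    n <- length(pos)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(pos[i] - pos[j]) <= maxGap) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    out <- lapply(split(pos, roots), sort)
    out[order(vapply(out, min, numeric(1)))]
}

## all-pairs nearest gene on 0-based half-open intervals with the
## documented tie-break (distance, gene start, gene id)
naiveNearest <- function(pChrom, pStart, pEnd, gChrom, gStart, gEnd, gId) {
    t(vapply(seq_along(pStart), function(i) {
        sel <- which(gChrom == pChrom[i])
        if (!length(sel)) return(c(NA_character_, NA_character_))
        d <- vapply(sel, function(j) {
            if (pEnd[i] <= gStart[j]) gStart[j] - pEnd[i]
            else if (gEnd[j] <= pStart[i]) pStart[i] - gEnd[j]
            else 0
        }, numeric(1))
        ord <- order(d, gStart[sel], gId[sel])
        c(gId[sel][ord[1L]], as.character(d[ord[1L]]))
    }, character(2)))
}

## upper tail by direct pmf summation
naivePoissonTail <- function(k, lambda) {
    if (k == 0L) return(1)
    1 - sum(exp(-lambda + (0:(k - 1)) * log(lambda) -
                lgamma(1:k)))
}

## BH step-up from the definitional formula
naiveBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
}
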