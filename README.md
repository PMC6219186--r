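# callingCards

Peak calling and downstream analysis for **transposon calling-card
experiments**, in which a piggyBac transposase fused to a chromatin
protein of interest deposits barcoded transposons ("calling cards") at
the genomic loci the protein visits. Sequencing the insertion sites
yields a permanent record of where the fusion protein bound; comparing
those insertions with a library made by the *unfused* transposase
separates protein-directed targeting from the transposase's own
background preferences. The package is written for analysts working
with insertion coordinate tables (qBED), a genome FASTA, gene models
(BED/GFF3) and a gene-level differential-expression table.

## The statistical core

piggyBac integrates only at TTAA tetranucleotides, so enrichment is
measured in **hops per TTAA site**. A *hop* is one independent
integration event, identified by the tuple (chromosome, position,
strand, barcode); read counts are metadata.

1. **Clustering.** Deduplicated foreground hops are clustered per
   chromosome by single linkage with a maximum inter-hop gap of 5 kb.
   Clusters with at least `minHops` (default 2) hops become candidate
   peaks; singletons are unclustered background.
2. **Local background rate.** For a peak with *k* hops spanning *s*,
   three nested windows are centered on the peak midpoint: the span
   itself, the span widened by ±1 kb, and by ±5 kb. In each window *w*
   the background library gives a rate
   *r<sub>w</sub>* = max(bg hops in *w*, 1) / TTAA sites in *w*,
   and the expected count is

   λ = (N<sub>fg</sub>/N<sub>bg</sub>) · max<sub>w</sub>(r<sub>w</sub>) · (TTAA sites under the peak).

   Taking the maximum of the three local estimates guards against
   underestimating uneven background density; the floor of one
   background hop prevents λ = 0 in background deserts.
3. **Test.** p = P(X ≥ k) for X ~ Poisson(λ), Benjamini–Hochberg
   corrected across candidates; significant means q ≤ 0.05.
4. **Annotation & statistics.** Peaks get nearest genes
   (bedtools-closest semantics with deterministic tie-breaks) and
   TSS distances (peak midpoint to nearest strand-aware TSS), compared
   against random genomic positions and against the raw background
   insertions with Mann–Whitney U tests.
5. **Expression integration.** Hops are summed per nearest gene;
   genes with more than 5 insertions are tested for association with
   expression response (adjusted p ≤ 0.01) by Fisher's exact test, and
   *strong* targets additionally change more than two-fold
   (|log2FC| > 1), partitioned into up- and down-regulated sets.

A deterministic synthetic-data generator (`simParams()`,
`simulateCallingCards()`) produces toy genomes, insertion libraries and
coupled expression tables with ground truth, at the same
hops-per-kilobase density as a real experiment; every pipeline claim in
the test suite is validated against that truth.

## Worked example

```r
library(callingCards)

report <- runPipeline(runConfig(outdir = "ccrun", seed = 1L))
print(report)
#> calling-card pipeline report (seed 1)
#>   hops: 5000 foreground / 5000 background
#>   clusters: 2149; candidates: 379; significant peaks: 51
#>   TSS distance, peaks vs random: U = 49, p = 5.64e-17 (median 367 vs 55076 bp)
#>   association (hops > threshold x responsive): Fisher p = 7.18e-21
#>   responsive fraction: 0.432 among high-hop, 0.000 among low-hop genes
#>   responsive fraction among targeted genes (> threshold hops): 0.686 (n = 51)
#>   strong targets: 14 up, 14 down
#>   truth recovery: recall 1.000, precision 0.980, gene accuracy 1.000
```

Reading the report: of 5,000 simulated foreground hops, 2,149 clusters
form, 379 carry ≥ 2 hops, and 51 are significantly enriched over the
background — recovering all 50 truly bound loci (recall 1.0) with one
false positive (precision 0.98) and every recovered locus assigned to
the correct gene. Significant peaks sit a median 367 bp from the
nearest TSS versus 55 kb for random positions (Mann–Whitney
p ≈ 6e-17). Genes with > 5 insertions are strongly associated with
expression response (Fisher p ≈ 7e-21); among genes adjacent to
significant peaks, 68.6% respond to depletion of the fused factor —
the generator's true responsive fraction is 0.7 — and 28 targets also
change more than two-fold.

The same stages are available piecewise — `readQbed()`, `dedupHops()`,
`ttaaIndex()`, `callPeaks()`, `annotatePeaks()`, `tssDistances()`,
`mannWhitneyU()`, `hopsPerGene()`, `associationTest()`,
`selectStrongTargets()` — and `runPipeline()` accepts real input files
through `runConfig(inputs = list(genome=, genes=, fg=, bg=,
expression=))`. `twoConstructAnalysis()` overlaps two fusion
orientations (peak and gene Venn summaries) and integrates the pooled
targets.

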