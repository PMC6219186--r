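---
title: "Calling-card peak calling and integration: models, parameters, design"
author: "callingCards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling-card peak calling and integration: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement and its model

A calling-card experiment fuses a piggyBac transposase to a chromatin
protein and lets the fusion deposit barcoded transposons wherever the
protein visits. After inverse PCR and sequencing, the data reduce to a
table of insertion coordinates. Two facts shape the statistics:

* piggyBac integrates **only at TTAA** tetranucleotides, so the natural
  exposure unit is the TTAA site, not the base pair. All rates in this
  package are *hops per TTAA*.
* The unfused transposase also integrates, with its own chromatin
  preferences. A **background library** made with unfused transposase is
  therefore required; the method never assumes a uniform genome-wide
  background, only that the background library samples the transposase's
  intrinsic landing distribution.

A **hop** is one independent integration event, identified by
(chromosome, position, strand, barcode, sample). Multiple reads of the
same tuple are PCR/sequencing replicates of one event and are collapsed
by `dedupHops()`, summing reads as metadata. Whether a peak statistic
should count reads or events is genuinely ambiguous in practice; we
count events, because barcodes exist precisely to demarcate independent
integrations, and read depth at one site reflects amplification, not
binding.

## Peak calling

Foreground hops on each chromosome are clustered by single linkage with
maximum gap `maxGap` (default 5000 bp): consecutive hops at most 5 kb
apart share a cluster. A cluster's span runs from its first TTAA to the
end of its last (`[min, max + 4)`), so every span is at least 4 bp.

For a cluster of $k$ hops the expected count $\lambda$ under the
background is estimated locally. Three windows are centered on the peak
midpoint: the span itself, and the span widened by `flankSmall` (1 kb)
and `flankLarge` (5 kb) on each side, clipped to the chromosome. In each
window $w$,

$$ r_w = \frac{\max(\text{bg hops in } w,\; \texttt{bgFloor})}{\text{TTAA sites in } w}, \qquad
\lambda = \frac{N_{fg}}{N_{bg}} \cdot \max_w r_w \cdot (\text{TTAA sites under the peak}), $$

and $p = P(X \ge k)$ for $X \sim \mathrm{Poisson}(\lambda)$, computed
through the regularized incomplete gamma function (`stats::ppois`),
which is stable far into the tail. Benjamini–Hochberg correction runs
across all candidate clusters (those with at least `minHops` hops,
default 2); `significant` means $q \le$ `fdrAlpha` (default 0.05).

Parameter rationale:

* **`maxGap` = 5000 bp** — the clustering scale of the assay; bound loci
  are narrow but repeated visits scatter hops over a few kb.
* **Three-window maximum** — "1 kb from the peak / 5 kb from the peak"
  can be read several ways; we use symmetric windows *extending* the
  peak by ±1 kb and ±5 kb around its midpoint, which makes the three
  windows nested and all centered directly under the peak. Taking the
  maximum of the three rates is deliberately conservative: a locally
  dense background (open chromatin, repeats) raises $\lambda$ rather
  than inflating significance.
* **`bgFloor` = 1 hop** — in background deserts a window may contain no
  background hops; a rate of zero would give $\lambda = 0$ and $p = 0$
  for any $k$. Flooring the window count at one hop means, in
  particular, that $\lambda \ge 1$ for every peak (the under-peak
  window alone guarantees it). This is the single strongest guard
  against desert artifacts and is configurable.
* **Depth scaling ON** — foreground and background libraries rarely
  have equal depth; the Poisson comparison is meaningless without the
  $N_{fg}/N_{bg}$ factor. With equal simulated depths it is exactly 1.
* **`minHops` = 2** — singleton clusters are reported (with $p$ and
  $\lambda$) but carry `candidate = FALSE`, an `NA` q-value and can
  never be significant; a single integration is indistinguishable from
  background.
* **Determinism** — peak calling contains no randomness; outputs are
  sorted by (chromosome, start); ties in nearest-gene assignment break
  by distance, then gene start, then lexicographic gene id.

## Annotation and TSS statistics

`annotatePeaks()` adds the nearest gene (closest-interval semantics,
distance 0 on overlap) and the distance from the peak *midpoint* to the
nearest strand-aware TSS. Midpoint rather than edge or summit is a
documented choice: spans are data-driven and asymmetric, and the
midpoint is the only summit-free location that does not depend on hop
order. Distances are reported unsigned (histograms fold around the
TSS); the signed offset is kept in `tssOffset` for stranded reporting.

The TSS-proximity claim is tested with a Mann–Whitney U comparison of
peak TSS distances against (a) an equal number of random genomic
positions (chromosome chosen proportional to length, position uniform;
seed recorded in the output) and (b) the TSS distances of *all raw
background insertions*, which controls for the transposase's own
preference for open chromatin near promoters. U is computed from
midranks; for pooled sizes $n_1+n_2 \le 16$ the p-value is an exact
enumeration over all $\binom{n_1+n_2}{n_1}$ assignments of the observed
pooled values (valid under ties, where classical exact tables are not),
otherwise a normal approximation with tie and continuity corrections.
The two-sided p is reported by default with the one-sided ("closer")
p alongside.

## Expression integration

Hops are summed over each gene's assigned peaks — candidate clusters
only, since singletons are unclustered background. Genes with more than
`hopThreshold` (5) insertions form the heavily targeted stratum; the
association with expression response (adjusted $p \le 0.01$, inclusive
by design) is tested two-sided by Fisher's exact test on the 2×2 table
of (hops > 5 / 1–5) × (responsive / not). The headline *responsive
fraction* is computed among genes adjacent to a significant peak with
more than 5 total hops — the "targeted genes" of the assay — while the
Fisher table uses all candidate-derived records so its sparse stratum
is populated. *Strong* targets additionally change more than two-fold
on the linear scale ($|\log_2 FC| > 1$) and are partitioned by sign.
Per-gene counting (rather than per-peak) is a documented choice: a gene
with several moderate peaks is biologically a heavier target than one
with a single equal-sized peak.

# The synthetic generator

`simParams()` / `simulateCallingCards()` generate a complete experiment
as a pure function of (parameters, seed): a uniform-random genome,
non-overlapping gene models, bound loci, two insertion libraries and a
coupled expression table with ground truth.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `nChroms` × `chromLength` | 5 × 15 Mb | 5,000 hops on 75 Mb is one hop per 15 kb — the density of a real library of ~200,000 insertions on a 3 Gb genome, and the quantity that controls clustering behavior |
| `nGenes`, `geneLength` | 500, 2 kb | one gene per 150 kb, enough TSSs for annotation to be non-trivial |
| `nBoundLoci`, `boundLocusWidth` | 50, 500 bp | narrow bound loci at distinct genes |
| `tssOffsetMax` | 500 bp | binding concentrated at promoters, so TSS-proximity statistics are testable; `placement = "random"` is the negative-control mode |
| `nFgHops`, `nBgHops` | 5,000 each | desk-scale libraries; at `backgroundMixture` 0.5 each bound locus receives ~50 hops |
| `backgroundMixture` | 0.5 | half of foreground hops follow the background distribution (undirected integration of the fusion) |
| `nBarcodes` | 40 | four sets of ten barcoded donors; a 500 bp locus holds ~2 TTAA sites, so the unique (position, strand, barcode) capacity (~160) must exceed the per-locus load (~50) |
| `deEffectMu`, `deSigma` | 1.5, 0.4 | responsive bound genes: \|log2FC\| ~ N(1.5, 0.4), sign Bernoulli(½); ~89% exceed the two-fold threshold |
| `responsiveFraction` | 0.7 | probability a bound gene truly responds to depletion |
| `nullSigma` | 0.2 | null log fold changes |

Event uniqueness is enforced at generation: collisions of (position,
strand, barcode) are re-drawn within the same bound locus (uniform over
its free combinations), so hop totals are exact and per-locus loads are
unbiased; a saturated locus spills into the background component with a
warning. Bound loci that land on TTAA-free sequence are re-sited (new
offset, then a fresh gene) with a warning. Adjusted p-values are
simulated directly — Uniform(0, 0.01] for true responders,
Uniform(0.01, 1] otherwise — rather than via a read-count model,
because the pipeline consumes a DE table; only the joint distribution
of (logFC, adjusted p, bound status) matters downstream.

**What the generator does not emulate:** chromatin bias in the
background (the real unfused transposase prefers open chromatin — the
method only requires a background *library*, not a bias model),
mappability and blacklist artifacts, multi-isoform TSSs, PCR duplicate
structure, and correlated binding between neighboring genes. Passing
tests therefore demonstrate the statistical machinery under the model's
own assumptions, not robustness to those real-data complications.

# Validation and known limitations

The test suite validates every kernel against an independent oracle
(pmf summation for the Poisson tail; exhaustive hypergeometric
enumeration for Fisher; pair-count enumeration for Mann–Whitney;
union–find for clustering; all-pairs search for nearest-gene), and the
pipeline end-to-end against generator truth: at the default conditions
(seed 1) all 50 bound loci are recovered with one false positive and
100% correct gene assignment; with 350 promoter-proximal loci the
TSS Mann–Whitney p is ~1e-97 against random positions while random
placement yields p ≥ 0.01 in 9/10 seeds; with 400 bound genes and
10,000 foreground hops the integration recovers the responsive
fraction 0.718 against a truth of 0.7 and shuffled expression abolishes
the Fisher association in 10/10 seeds. These problem sizes were chosen
so each binomial check has a standard error comfortably inside its
tolerance band.

One limitation is measured and worth stating plainly. Under a true null
(foreground drawn from the background distribution at the default
density), candidate clusters' p-values are mildly anticonservative:
pooled over ten seeds, 6.9–7.0% of candidates have p < 0.05, and BH at
0.05 admits 0–3 significant peaks per run instead of none. The cause is
structural: the Poisson test evaluates $k$ hops against the expectation
in the *minimal* span enclosing them, but single-linkage clustering is
a scan statistic — uniform hops form runs whose length follows a
geometric law with ratio $q = P(\text{gap} \le 5\,\text{kb})$, so
4-hop null clusters occur with frequency $q^2$ (~8% at one hop per
15 kb) while Poisson($\lambda \approx 1$) assigns them $p = 0.019$. The
window-maximum rule and the background floor mitigate but cannot remove
selection bias in the candidate set. Practical consequences: treat
marginal peaks (q-values near the threshold, k ≤ 4) with caution, and
prefer the joint evidence of peak significance, TSS proximity and
expression response, which is how the target-gene sets here are
defined. Sparser libraries calibrate better; denser ones are worse.

Degenerate inputs are handled explicitly: empty foregrounds return
empty peak sets; an empty background is an error (the method is
undefined without one); unknown chromosomes in TTAA counting return 0
with a warning; peaks on chromosomes without annotation are reported NA
with a warning rather than dropped; Fisher tables with a zero margin
give p = 1; identical Mann–Whitney samples give p = 1.

# Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state (`withr::with_seed`); `simulateCallingCards()`
derives stage seeds as seed, seed+1, seed+2, seed+3. `runPipeline()`
records its seed in the report and in `report.json`, skips stages whose
outputs are newer than their inputs (re-runs are idempotent), and
leaves a `<stage>.partial` marker if a stage fails.

```{r example}
library(callingCards)
report <- runPipeline(runConfig(outdir = "ccrun", seed = 1L))
print(report)
```
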