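---
title: "Methods: models, parameters and design choices in creglink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in creglink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the statistical
model behind CRE–gene linkage calling, the conventions every module follows,
what the synthetic generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## Coordinates and interval semantics

All internal coordinates are 0-based half-open (BED convention). GTF input is
converted at the boundary (`start - 1`); the TSS of a `+` gene is
`body.start`, of a `-` gene `body.end - 1`. Two intervals overlap iff
`a.start < b.end && a.end > b.start`; bookended intervals (sharing no base)
do not overlap, and are therefore *not* merged when building the union CRE
set. Union CREs are the maximal intervals of the transitive overlap closure
of all samples' peaks; every input peak is contained in exactly one union
CRE, which is asserted at construction time. Samples of different species are
never merged into one union set.

## Quality control

Per cell we compute four metrics and apply six strict inequalities
(`>`/`<`, never `>=`): RNA reads in (1000, 25000), ATAC reads in
(1000, 100000), nucleosome signal < 2, TSS enrichment > 1.

* *RNA reads* are RNA matrix column sums (the annotation "reads vs UMIs" is
  unspecified upstream; column sums are the only quantity derivable from the
  count matrix alone).
* *Nucleosome signal* is the count-weighted ratio of mononucleosome-length
  fragments (147–294 bp, inclusive) to nucleosome-free fragments (< 147 bp).
  It is undefined (NA) for a cell with no sub-147 bp fragments, and an
  undefined value fails the filter — the conservative reading.
* *TSS enrichment* aggregates per-base fragment coverage over ±1000 bp
  windows around every TSS; the score is the mean coverage of the central
  100 bp bin over the mean coverage of the two outermost 100 bp flanks
  (the ENCODE-style convention). Degenerate cases: all-zero window → 1.0
  (neutral); zero flanks with nonzero center → a configurable cap
  (default 20), so a single promoter fragment cannot yield an infinite
  score. The metric is a ratio and hence invariant to sequencing depth.

## Normalization and reductions

RNA: `ln(1 + v * 10^4 / T)` per cell; variable features ranked by plain
variance of the log-normalized values (deterministic and dependency-free; a
deviation from the variance-stabilizing fit used by the popular toolkit —
only "top N variable features" is specified upstream, and ties are broken by
feature order). Scaling centers each feature to mean 0 / sd 1 with
zero-variance features set to 0. PCA is an exact SVD with a fixed sign
convention (the largest-magnitude loading of each component is positive), so
results are bit-reproducible without a seed.

ATAC: the peak×cell matrix counts, for each cell, the summed duplicate count
of fragments overlapping each peak (a fragment spanning two peaks counts in
both). Features with total count below 5 are dropped (`>= min.cutoff`
retention, matching the cited tool's semantics). TF-IDF is
`ln(1 + TF * IDF * 10^4)` with `TF = count/cell_total`,
`IDF = n_cells/feature_total`; LSI is a truncated SVD of that matrix. The
first LSI component tracks sequencing depth, so downstream consumers use
components 2–40; this is carried in the reduction's `component_range`.

## Joint clustering and annotation

The weighted-nearest-neighbor algorithm of the upstream toolkit is *not*
re-implemented (it is a separate publication's method used as
infrastructure). Substitute: each embedding is standardized per component,
PCA dims 1–50 and LSI dims 2–40 are concatenated, a k = 20 Euclidean k-NN
graph is built (neighbor sets include the point itself), and edges are
weighted by the Jaccard overlap of neighbor sets (an SNN graph). Louvain at
resolution 1 with a fixed seed partitions it. Clustering only feeds
annotation and grouping, so the substitution affects no linkage statistics.

Annotation computes Spearman correlations (average ranks on ties) between
cluster pseudobulks and reference pseudobulks on the intersection of feature
ids, using the top 3000 variable genes *computed on the reference side* —
the reference is the stable, curated object, while a small query cluster's
variances are noisy (the upstream description does not say which side).
Argmax assigns the label; ties break by reference label order. Without a
reference, every cluster receives the sample's source name.

## The linkage model

For gene *g* with expression vector *e* (log-normalized, QC-passed cells)
and candidate peak *p* (full interval intersecting
`[tss − 50000, tss + 50000]`) with log-normalized accessibility *a*:

1. genes and peaks detected in fewer than `min_cells = 10` cells are
   dropped;
2. `r_obs = cor(e, a)` (Pearson);
3. a background of `n = 200` peaks is drawn from the pool excluding the
   target and all candidates of the current gene, nearest in standardized
   feature space — GC fraction (when a GC table or FASTA-derived values are
   supplied), `log1p(total accessibility)`, `log(width)`. GC matching is
   optional so the core stays dependency-free; accessibility and width are
   always matched;
4. `z = (r_obs − mean(r_bg)) / sd(r_bg)` (unbiased sd),
   `p = 1 − Φ(z)` upper tail. A background with zero sd, or a constant
   expression/accessibility vector, skips the pair rather than fabricating
   a value;
5. links with `p < 0.05` and `|r| > 0.05` are retained.

The one-sided upper tail means negative links are never significant; a
`two_sided` switch exists (default off). The cutoffs are the adopted
defaults of the tool the pipeline names; they are plain configuration, since
no cutoff is stated upstream. Correlations use log-normalized values on both
modalities. Duplicate (gene, union CRE, sample) rows after remapping keep
the smallest p-value.

Under the null (independent Poisson-lognormal counts) the z-test rejects at
~5%, verified by the calibration acceptance test (rejection fraction
required in [0.03, 0.07] at 500 pairs).

## Cross-sample layer

Presence of a linkage in a tissue is binary: at least one sample of that
tissue carries the (gene, union CRE) pair; linkage strength is ignored for
presence counting, and the distribution is over *distinct* (gene, union CRE)
keys. The tissue-specificity rule is evaluated with strict inequalities:
present in more than half of the target tissue's samples and less than half
of every other tissue's (at 2 samples per tissue this means both target
samples and zero others). The optional cell-type restriction — a linkage
peak must overlap a cell-type-level peak — is applied *before* presence
matrices are built. The region view normalizes per-group binned coverage by
the group's genome-wide fragment total (×10⁴), so groups of different depth
are comparable; doubling every fragment count of a group provably leaves its
track unchanged.

## TF enrichment

The external composite "binding score" of the named TF-annotation service is
replaced by a transparent statistic: each TF's peak set yields a 2×2 table
of query CREs vs the rest of a background universe (default: the union CRE
set), hit = overlapping ≥ 1 TF peak (multiple peaks count once). The
one-sided Fisher p is the hypergeometric upper tail; the odds ratio is the
raw cross-product ad/bc (∞ and 0 at the boundaries); BH adjustment ranks
TFs, ties by odds ratio then name.

## The synthetic world

The generator emulates exactly the data shapes the pipeline consumes, with
planted, recorded truth. Defaults (the standard test corpus): 3 tissues × 2
samples, 300 cells/sample, 200 genes on a toy 2-chromosome genome (genes
120 kb apart so TSS windows never touch a neighbor's peaks), 3 peaks per
gene — a 500 bp promoter peak covering the TSS and distal peaks ±20 kb —
600 peaks total, one planted linked (distal) peak per gene at target
correlation 0.6, 30% of links tissue-specific.

Counts are Poisson-lognormal: per gene, a per-cell latent activity
`a ~ Lognormal(0, 0.6)`; gene counts `~ Pois(λ_g a)` with
`λ_g ~ Lognormal(log 8, 0.4)`; a linked peak's counts `~ Pois(λ_p a^γ)`
with `λ_p ~ Lognormal(log 4, 0.3)`; unlinked peaks get independent latents.
γ is calibrated by grid search with common random numbers so the realized
Pearson correlation of *log-normalized* values hits the target — the
calibration includes the scale factor / expected-cell-total ratio, because
library-size log-normalization visibly compresses correlations (without it,
realized r ≈ 0.48 instead of 0.60). Fragments are written one per unit
count, fully inside their (per-sample jittered) peak, with lengths drawn
from 60–140 bp (65%) and 160–280 bp (35%) so nucleosome signal lands near
0.55; promoter peaks cover the TSS so TSS enrichment is high. The intended
peak×cell count matrix is reconstructed *exactly* by `feature_matrix` on
the emitted fragments (an integer-equality test).

**Closed chromatin outside the home tissue.** A planted tissue-specific CRE
emits no fragments in samples of other tissues. This choice matters: if
such CREs were fully open everywhere, the ~5% per-sample false-positive rate
of the p < 0.05 linkage cutoff would place a spurious link in some other
tissue for ~20% of planted CREs, and the strict "< half" rule (zero
tolerance at 2 samples/tissue) would then reject them — capping end-to-end
sensitivity near 0.8 regardless of implementation quality. Closure is also
the biologically realistic reading: a tissue-specific enhancer is closed
chromatin elsewhere, and the per-sample peak calling the pipeline assumes
would not report a peak there at all.

What a green end-to-end test does **not** establish: the generator has no
doublets, no ambient contamination, no batch effects, no distance-dependent
linkage structure, a caricature TSS profile (coverage only where peaks are),
and identical peak layouts across samples up to ±30 bp jitter. It validates
the statistical machinery and the cross-sample bookkeeping, not robustness
to real-data artifacts.

The tiny preset (2 tissues × 2 samples, 80 cells, 30 genes) raises per-gene
means (gene ~60, peak ~15) because the absolute QC read-count thresholds
(> 1000) cannot otherwise be met with so few features; it exists for smoke
tests, not for power statements.

## Numerical choices and degenerate inputs

Deterministic everywhere: exact SVDs with sign conventions, stable ordering
on ties (feature order, pool order, reference label order, genomic
position), seeded Louvain and seeded generators — identical seeds give
byte-identical serialized outputs, which is itself an acceptance test.
Degenerate inputs error early and name the offender: zero-total cells in
normalization, empty barcode intersections, genes without strand, unmapped
peaks during remapping, unknown tissues, unknown CLI/config keys.

## Known limitations

Variable-feature selection is plain variance, not a mean-variance fit; the
SNN/Louvain substitute will not reproduce upstream WNN cluster boundaries
exactly; GC matching requires a user-supplied GC table; SVDs are dense
(fine at package scale, not for millions of cells); p-values are not
multiplicity-adjusted across genes in linkage calling (matching the adopted
tool's behavior) — the tissue-specificity layer, not the per-sample FDR, is
what provides cross-sample robustness.
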