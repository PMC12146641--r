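# creglink

Comparative analysis of gene regulation from single-cell multiome (joint
RNA + ATAC) data, as a self-contained R toolkit.

Most single-cell multiome studies look at one tissue at a time, so they can
tell that a cis-regulatory element (CRE, an ATAC peak) is linked to a gene's
expression, but not whether that regulatory relationship is specific to the
tissue at hand or ubiquitous. `creglink` implements the full per-sample
processing pipeline and the cross-sample comparison layer needed to answer
that question offline, on your own samples or on synthetic corpora with
planted ground truth:

* **QC** — per-cell RNA/ATAC read counts, nucleosome signal
  (mononucleosome 147–294 bp over sub-147 bp fragments), TSS enrichment
  (center/flank coverage ratio in ±1 kb windows), and the six-criteria cell
  filter (all inequalities strict: RNA reads in (1000, 25000), ATAC reads in
  (1000, 100000), nucleosome signal < 2, TSS enrichment > 1).
* **Matrices** — library-size log-normalization `ln(1 + v·10⁴/T)`, variance-
  ranked variable features, per-feature scaling, PCA; fragment×peak overlap
  counting, `min.cutoff ≥ 5` feature filtering, TF-IDF
  `ln(1 + TF·IDF·10⁴)`, LSI (truncated SVD, components 2–40 used
  downstream); pseudobulk means and 100 kb genome-bin QC pseudobulks.
* **Clustering & annotation** — a shared-nearest-neighbor graph over the
  standardized, concatenated PCA (1–50) and LSI (2–40) embeddings, Louvain
  at resolution 1, and Spearman-correlation annotation against reference
  pseudobulks on the top 3000 variable genes (argmax label).
* **CRE–gene linkage** — for each gene, candidate peaks within 50 kb of the
  TSS; observed Pearson r between log-normalized expression and
  accessibility; a background of 200 peaks matched on (GC when available,
  log1p total accessibility, log width); then

      z = (r_obs − mean(r_bg)) / sd(r_bg),   p = 1 − Φ(z)

  retaining links with p < 0.05 and |r| > 0.05.
* **Cross-sample comparison** — union CRE set (transitive merge of all
  samples' peaks, bookended intervals kept separate), linkage remapping onto
  it, the tissue-presence histogram (in how many tissues is each distinct
  (gene, CRE) linkage present), tissue-specific gene-linked CREs (present in
  **more than half** of the target tissue's samples and **less than half**
  of every other tissue's samples), a cell-type peak restriction, and a
  single-sample region view (depth-normalized per-group coverage tracks,
  ±10 kb flanks).
* **TF enrichment** — per-TF ChIP-seq peak sets scored by one-sided Fisher
  exact tests of query-CRE overlap against a background CRE universe, BH-
  adjusted and ranked.
* **Synthetic data** — a Poisson-lognormal multiome generator with planted
  links of a target correlation (γ-calibrated), planted tissue-specific CREs
  (closed chromatin outside their tissue), planted TF binding, and exact
  ground truth, emitting all the exchange formats (MTX, fragments TSV, BED,
  gene TSV).

## Worked example

```r
library(creglink)

corpus <- simulate_corpus(tiny_spec(seed = 42))   # 2 tissues x 2 samples
um <- build_union_cres(lapply(corpus$samples, function(b) b$peaks))

detected <- do.call(rbind, lapply(corpus$samples, function(b) {
  pr <- process_sample(b, seed = 1)               # QC -> reductions -> clusters
  link_sample(pr, b$genes, linkage_config(n_background = 60, seed = 1))
}))

remapped <- remap_linkages(detected, um)
tissue_presence_distribution(remapped, corpus$truth$tissue_of)
#>   n_tissues count fraction cumulative_fraction
#> 1         1    17    0.436               0.436
#> 2         2    22    0.564               1.000

call_tissue_specific(remapped, um$union_cres, corpus$truth$tissue_of, "tissue01")
#>   gene_id cre_index chrom  start    end
#> 1 gene001         1  chr1  39470  40030
#> 2 gene003         7  chr1 279481 280029
#> ...                                       (5 rows)
```

Reading the output: 112 linkages were detected across the 4 samples (e.g.
gene001 ~ chr1:39492-40005, r = 0.56, z = 5.05, p = 2.2e-07). After
remapping onto the 90 union CREs, 17 of the 39 distinct linkages are present
in one tissue only and 22 in both — matching the generator's plant of
tissue-specific and shared links. The tissue-specificity rule then recovers
exactly the 5 CREs planted as specific to `tissue01`.

## Command line

Every stage is also a subcommand (outputs are plain files plus a
`manifest.json` per stage):

```sh
Rscript inst/cli/creglink simulate --preset tiny --seed 7 --out run/corpus
Rscript inst/cli/creglink qc       --sample run/corpus/tissue01_s1 --out run/qc/tissue01_s1
Rscript inst/cli/creglink process  --sample run/corpus/tissue01_s1 --out run/proc/tissue01_s1
Rscript inst/cli/creglink link     --sample run/corpus/tissue01_s1 --proc run/proc/tissue01_s1 --out run/links/tissue01_s1
Rscript inst/cli/creglink union    --corpus run/corpus --linkdir run/links --out run/union
Rscript inst/cli/creglink presence --union run/union --corpus run/corpus --out run/presence
Rscript inst/cli/creglink specific --union run/union --corpus run/corpus --tissue tissue01 --out run/spec
Rscript inst/cli/creglink tfenrich --query q.bed --background run/union/union_cres.bed --tfdir tfbeds --out run/tf
Rscript inst/cli/creglink regionview --sample run/corpus/tissue01_s1 --proc run/proc/tissue01_s1 --gene gene001 --out run/rv
```

QC thresholds, linkage cutoffs and all other parameters can be overridden
with flags (`--pvalue-cutoff 0.01`) or a flat `key = value` file via
`--config`; unknown keys are rejected.

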