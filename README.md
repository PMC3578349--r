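# brainpatterns

Dominant regional gene-expression patterns in bulk brain transcriptomes, and
their conservation across species.

Bulk expression in a brain region averages over the cell types composing the
tissue, and the glia-to-neuron ratio varies systematically across regions. The
first principal component of a standardized gene × region matrix therefore
splits into two anti-correlated poles: an **oligodendrocyte-enriched** pattern
(positive scores, by the convention that an oligodendrocyte marker anchor
scores positive) and a **neuron-enriched** pattern (negative scores).
`brainpatterns` implements, as tested R functions:

* preprocessing of gene × region matrices: probe collapsing (per-sample mean),
  replicate averaging by structure name, white-matter sample exclusion, a
  25th-percentile low-signal filter on per-gene mean *or* SD, and per-gene
  z-scoring;
* PCA over genes as observations (per-gene scores, per-region loadings,
  variance fractions) with anchor-based sign orientation, extraction of the
  top-n pattern gene sets, averaged pattern profiles, per-region
  oligodendrocyte/neuron marker ratios, and per-division loading summaries;
* ranked-list marker enrichment: ROC AUC (ties = 1/2) with a rank-sum normal
  approximation p-value,
  `AUC = P(marker outranks non-marker)`, computed per cell type with per-type
  direction conventions;
* cross-species comparison: aggregation to shared parent structures
  (hemispheres first), homolog matching (many-to-many groups averaged), joint
  quantile normalization, a both-species expression filter,
  pairwise-complete Spearman rho/p/q per gene and per region
  (Benjamini-Hochberg FDR), a 20-shuffle gene-label permutation null, and
  ±0.30 threshold-excess counts against it;
* reporting: Ward/Euclidean clustering of regions with Newick export,
  correlation of gene scores with external covariates, overlap with external
  discordant-gene lists, and a consolidated JSON run report;
* a synthetic-data generator that plants the assumed structure (cell-type
  composition gradient, ≥10× fold-enriched markers, conserved gene-specific
  signatures, rank-reversed discordant genes, replicates, NAs) so every stage
  is verifiable by parameter recovery.

## Worked example

The numbered scripts under `analysis/` run the two workflows end to end on
simulated data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_within_pca.R
Rscript analysis/03_cross_species.R
Rscript analysis/04_report.R
```

On the default seed this prints, for the within-species workflow:

```
retained 1139 of 1972 genes after the low-signal filter
PC1 explains 15.6% of variance (PC2 1.5%, PC3 1.5%)
astrocyte marker AUC = 0.461 (direction +, p = 0.26)
neuron marker AUC = 1.000 (direction -, p = 3e-59)
oligodendrocyte marker AUC = 1.000 (direction +, p = 2.5e-60)
neuron vs oligodendrocyte averaged patterns: rho = -0.99
```

The planted gradient dominates PC1; neuron and oligodendrocyte markers sit at
opposite poles of the PC1 ranking (AUC 1.0 on their respective directions),
while the flat-planted astrocyte markers show no enrichment (AUC ≈ 0.5), and
the averaged marker patterns are strongly anti-correlated across regions. For
the cross-species workflow:

```
matched matrices: 1503 genes x 58 parent regions
per-gene rho: mean 0.767, min -0.96, max 0.99
per-region rho: mean 0.95 +/- 0.004
vs the 20-shuffle null: +1326.7 genes above rho = 0.30, +99.8 below -0.30
planted discordant genes retained: 137, of which 100% have rho < 0
```

Conserved genes correlate strongly across the 58 matched regions; the 10% of
genes whose regional profile was rank-reversed in species B all come out
negatively correlated, and the excess of genes below rho = −0.30 over the
gene-label permutation null (+99.8) tracks the planted-and-retained count.

The same computations are available directly, e.g.:

```r
library(brainpatterns)
cfg <- run_config("within", simulation = sim_config(seed = 1), seed = 1)
w <- run_workflow(cfg)
w$enrichment            # per-cell-type AUC, p, direction
w$pca$variance_fraction # per-component variance
w$anticorrelation       # averaged neuron vs oligodendrocyte pattern rho/p
```

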