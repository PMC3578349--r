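---
title: "Regional brain expression patterns: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional brain expression patterns: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainpatterns)
```

## The scientific question

Bulk expression measured in a brain region is a weighted average over the cell
types that make up the tissue. Because the glia-to-neuron ratio varies
systematically across brain regions, the dominant axis of variation in a
regional transcriptome tends to be a pair of anti-correlated patterns: genes
enriched in oligodendrocytes rise where myelinated tissue is abundant, and
genes enriched in neurons fall, and vice versa. `brainpatterns` implements the
analysis chain that extracts this axis from a gene-by-region matrix, measures
how strongly cell-type marker genes concentrate at its poles, and asks whether
per-gene regional patterns are conserved between two species measured on
different platforms.

Two workflows bind the stages together:

* **within** — preprocess (replicate averaging, white-matter exclusion,
  low-signal filtering, per-gene standardization), PCA with a marker-anchored
  sign convention, pattern extraction, and ranked-list AUC marker enrichment.
* **between** — aggregation of both species to shared parent structures,
  homolog matching, joint quantile normalization, a joint expression filter,
  pairwise-complete Spearman correlations per gene and per region with
  Benjamini-Hochberg q-values, and a gene-label permutation null.

## The model behind the statistics

For a gene $g$ in a sample of region $r$ the generator (and, implicitly, the
analysis) assumes

$$x_{gs} = \sum_c p_{r(s),c}\,\mu_{gc} + s_{gr} + \varepsilon_{gs},
  \qquad \varepsilon_{gs} \sim N(0, \sigma^2),$$

truncated at zero: a composition mixture (proportions $p$, cell-type means
$\mu$), a conserved gene-specific regional signature $s_{gr}$, and measurement
noise. PCA is run on the standardized gene-by-region matrix with genes as
observations, so each gene gets a score per component and each region a
loading; the first component picks up the composition axis. Enrichment of a
marker set in the PC1 ranking is the probability that a random marker outranks
a random non-marker (ROC AUC, tied pairs counting one half), with a two-sided
p-value from the normal approximation to the rank-sum statistic with tie and
continuity corrections. Scores are negated for gene sets expected at the
negative pole (neuron markers), so enrichment is always reported on the
informative side.

Cross-species conservation is a per-gene Spearman correlation across matched
parent regions after joint quantile normalization, with pairwise-complete
deletion for missing values, midranks for ties and a two-sided p-value from
the $t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$. The empirical null
shuffles one species' gene labels without replacement (20 shuffles by
default; the identity permutation is not excluded) and recomputes the rho
vector per shuffle; excess counts above/below a $\pm 0.30$ threshold are
reported against the mean null count.

## What the generator plants, and why

`sim_config()` defines the study conditions:

* **Composition gradient.** The neuron fraction falls linearly from 0.50 to
  0.30 along the region axis while the oligodendrocyte fraction rises from
  0.12 to 0.32; the two trends sum to a constant. `gradient_strength` $g$
  mixes the trend with uniform noise in the same windows, weighted $1-g$, so
  $g=1$ is a deterministic monotone gradient and $g=0$ leaves the two
  fractions independent (their correlation is centred on zero — a property
  the null tests rely on). Named non-gradient types (astrocyte by default)
  are held exactly constant — "flat-planted" — and an unnamed residual
  fraction (microglia, endothelium, ...) absorbs compositional closure, so
  rows sum to one exactly without coupling the astrocyte fraction to the
  gradient noise. A two-type configuration uses the complement instead.
* **Markers.** Each marker gene's $\mu$ is at least `fold_enrichment`
  (default 10, drawn in $[10, 15]\times$) above every other type; non-marker
  genes carry only a modest $\pm 10\%$ type contrast. This matters for the
  permutation null: if every gene rode the composition axis, randomly paired
  genes would correlate at $\pm|\rho|$ just as strongly as matched ones and
  threshold-excess counts would be uninterpretable.
* **Gene-specific signature** (`gene_signal_sd`, default 0.15 expression
  units, about 10–15% of a typical mean level). Real regional transcriptomes
  are dominated by gene-specific patterns — the composition axis explains
  only a minority of variance — and cross-species conservation of non-marker
  genes rests on exactly this component, which both simulated species share.
  Setting it to 0 yields a pure mixture model (used for the all-null pair,
  together with `gradient_strength = 0`, so the two species share nothing).
* **Discordance.** A `discordant_fraction` of non-marker genes has its
  regional profile rank-reversed in species B only: a permutation of the
  profile values, so the marginal distribution is untouched and the
  discordance is purely pattern-level, but the cross-species correlation is
  driven towards $-1$ rather than merely towards zero. Markers are exempt
  because reversing a marker in one species would falsify that species'
  marker catalogue.
* **Noise, replicates, missingness.** Gaussian noise truncated at zero
  (expression energies are non-negative); `n_replicates_per_region` samples
  share a structure name; missing entries are placed completely at random,
  emulating in-situ-hybridization-style NA reporting. "Low noise" in the
  recovery analyses means `noise_sd = 0.02` (~2% of a mean expression level);
  the headline within-species run uses `noise_sd = 0.2 x mean(mu)`.

What the generator does **not** emulate: probe-level microarray artefacts,
spatial registration error, laminar cortical structure, platform-specific
dynamic range differences, and non-random missingness. Passing recovery tests
therefore demonstrates that the pipeline's statistics behave as designed under
the assumed mixture-plus-signature model, not that any particular biological
dataset satisfies that model.

## Numerical conventions

* Standard deviations use the $n-1$ denominator everywhere; quantiles use
  linear interpolation of order statistics (R type 7).
* The low-signal filter computes both thresholds (25th percentile of per-gene
  means and of per-gene SDs) on the full pre-filter gene set and removes a
  gene only when *strictly* below a threshold; ties are kept. Genes with
  fewer than three non-missing samples are removed beforehand.
* Per-gene means/SDs and all averaging steps use available (non-missing)
  values; PCA input must be complete, so genes with any missing region value
  are dropped (and counted) before standardization.
* Joint quantile normalization pools the columns of both matrices; the
  reference is the position-wise mean of each column's sorted values, columns
  with missing entries contributing through linear interpolation at
  proportional quantile positions $(\mathrm{rank}-1)/(m-1)$. Consequences:
  any two columns with the same number of non-missing values end up with
  identical sorted values, and the operation is exactly idempotent on
  complete data. For columns containing NAs, re-application can move values
  by a small interpolation residual (the recomputed reference interpolates
  interpolated values); ranks and NA positions are always preserved. Exact
  idempotence under missingness is unattainable in any scheme that averages
  per-column interpolants, so the package documents rank preservation as the
  guarantee in that regime. A per-matrix (`method = "separate"`) variant is
  available.
* Component orientation generalizes the single-anchor convention (an
  oligodendrocyte marker scores positive on PC1) to the mean over an anchor
  set, for robustness when one anchor is filtered out. Orientation is
  idempotent and recorded.
* Ties in `top_pattern_sets` break lexicographically by gene ID; clustering
  uses Euclidean distances with Ward's criterion (`hclust` method
  `"ward.D2"`, heights on the distance scale) and `hclust`'s lowest-index
  merge convention for equal distances.
* Spearman results with fewer than `min_overlap = 5` complete pairs are
  flagged non-computable rather than dropped or errored; q-values are
  computed over the computable p-values only.
* Many-to-many homology groups (connected components of the gene-pair graph)
  are averaged per species into one row per group, mirroring the treatment of
  probes and replicate regions; each group is labelled by its
  lexicographically smallest species-A gene.
* The joint expression filter removes a gene only when its mean is strictly
  below the per-species quantile threshold in *both* species.
* The threshold-excess comparison uses the mean count across shuffles (a
  single aggregated null), and the permutation null draws permutations
  uniformly — with realistic gene counts the identity permutation has
  negligible probability.

## Problem sizes and open choices

The recovery analyses run at 2,000 genes x 100 regions (100 markers per cell
type) for the within-species workflow, 1,000 genes x 20 regions for the
all-null pair, and 2,000 genes x 58 matched regions with 10% discordance for
the detection analysis, each with 20 label shuffles — sizes at which every
property of interest is measurable with comfortable margins while a full run
of the pipeline stays in the seconds-to-minutes range.

Where the design was genuinely open, the package chose:

* PCA retains all `min(genes, regions)` components and reports the top three
  variance fractions; nothing downstream depends on a retention cut-off.
* The quantile thresholds of the low-signal filter are both computed on the
  full pre-filter gene set (not after applying each other).
* Quantile normalization is pooled across the two species (comparability of
  values is the point of the step); the per-matrix variant sits behind a
  flag.
* Astrocyte-style weakly polarized sets are reported on the `+` direction
  with `max(AUC, 1-AUC)` as a labelled extra column, since their informative
  direction is not fixed by convention.
* The detection contract for planted discordance is evaluated against the
  planted genes *retained* by the joint expression filter; the filter removes
  about a quarter of genes regardless of discordance, so the raw planted
  count is not observable downstream.
* There is no shell entry point: the workflows are R functions
  (`run_workflow()` over a validated `run_config()`, YAML-loadable), and the
  numbered scripts under `analysis/` are the command-line surface.

## Known limitations

Dendrogram leaf order depends on the agglomeration implementation's
tie-breaking and is documented rather than canonical. The rank-sum p-value is
a normal approximation — exact enumeration is used only as a test oracle — so
p-values for very short lists are approximate. The permutation null in data
with a strong shared axis has heavy symmetric tails (randomly paired
axis-following genes correlate at $\pm|\rho|$); threshold-excess counts
should be read against that null, not against zero. And the generator's
simplifications listed above mean recovery results bound what the pipeline
can do under its own assumptions, not under arbitrary real data.
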