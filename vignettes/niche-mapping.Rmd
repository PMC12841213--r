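---
title: "Mapping innate-like T-cell niches in spatial transcriptomics: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping innate-like T-cell niches in spatial transcriptomics: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iltcmap)
```

## The problem

Innate-like T cells — γδT, MAIT and iNKT — are rare, rapid-response
lineages positioned at epithelial barriers. In inflamed skin their
spot-level transcriptional footprints can be mapped with Visium-style
spatial transcriptomics, but each ~55 µm spot samples a mixture of cells, so
the unit of inference is a *niche*: a spot whose expression is dominated by
a subset's programme. `iltcmap` implements the full chain from spot counts
to niche calls, layer-stratified frequencies, severity associations and
spatial patterning, plus a CITE-seq stage for the circulating counterparts.
Everything is driven by a synthetic generator with known ground truth, so
each stage carries a parameter-recovery test.

## Deconvolution model

A spot's depth-normalised expression vector $y$ (counts per 10k, linear
scale) is modelled as a non-negative combination of reference cell-type
profiles $P$ (columns scaled to unit gene-sum):
$$\hat x = \arg\min_{x \ge 0} \lVert W (P x - y) \rVert_2 .$$

Two choices deserve comment.

**Linear scale, no log.** The mixture model is additive in expression;
log-transforming breaks that additivity, so NNLS operates on linear
normalised counts. Proportions are $\hat x / \sum_k \hat x_k$ and are
invariant to the overall depth scale (tested as a scale-equivariance
property of the solver).

**Noise-adapted weights.** UMI counts are negative binomial with variance
$\mu + \phi\mu^2$: in absolute terms, high-expression genes are by far the
noisiest, yet ordinary least squares weights them the most. Unweighted NNLS
is therefore fragile at realistic overdispersion — on the generator's
default conditions its mean absolute proportion error is roughly double
that of the weighted fit. The default `weighting = "nb"` runs two passes:
first with weights $1/\sqrt{\bar m_g + 0.5\,\bar m_g^2 + 0.1}$ from the
per-gene mean expression $\bar m_g$, then — after moment-estimating a global
$\phi$ from the Pearson residuals of the fitted spot means — with weights
equal to the inverse fitted noise standard deviation. The weights are
insensitive to the exact $\phi$ (the $\mu^2$ term dominates for most
genes); `weighting = "none"` restores the plain fit. The solver itself is a
Lawson–Hanson active set with tolerance $10^{-10}$: deterministic and
effectively exact for the ≤ 10 columns of a cell-type design.

**Degenerate designs.** All-zero reference columns are pinned at zero;
columns exactly proportional to an earlier column (equality after scaling
to unit norm) are collapsed before the fit and the fitted component split
equally afterwards, so collinear duplicates give a deterministic answer
instead of an arbitrary vertex of the solution set. Both cases flag the
spot `degenerate`. All-zero spots are flagged `zero_spot` with zero
proportions.

## Niche calling

Calling is two-staged, mirroring how a cytometrist would gate:

1. **T gate.** A spot is eligible when its summed T-lineage proportion
   reaches its sample's *adaptive threshold*: the per-sample
   linear-interpolation quantile (default 0.80) of the T fraction, floored
   at 0.05. Per-sample quantiles adapt the gate to immune-cell density,
   which varies strongly between biopsies; the floor prevents the gate
   collapsing to noise in T-poor samples. The comparison is inclusive
   (`>=`) so the all-equal degenerate case behaves deterministically.
   Samples with fewer than 10 spots fall back to the floor.
2. **Dominance.** Among eligible spots the label is the subset with the
   largest *within-sample z-scored* signature score, required to be
   positive. z-scoring makes signatures of different sizes and baselines
   comparable; raw score magnitudes are not. Exact ties break by the larger
   deconvolved fraction of the corresponding subset, then by the fixed
   order γδT > MAIT > iNKT. A subset with no available signature is skipped
   with a warning (mirroring panels where iNKT cannot be assessed).

Signature scores are means of log-normalised expression over the set's
genes (`plain_mean`), optionally corrected by subtracting a size-matched
control set drawn from 25 expression-matched bins, 50 control genes per
signature gene, seeded (`control_corrected`). The shipped signature file
(`inst/extdata/iltc_signatures.gmt`) holds editable defaults built from
canonical lineage markers (TRDC, TRGC1/2, KLRD1, B2M for γδT; KLRB1, DPP4,
CXCR6, IL7R for MAIT); it is a starting point, not a curated resource, and
any GMT can be substituted.

## Frequencies, severity and the imbalance index

Niche frequencies are plain percentages over the spots of each sample ×
layer cell (cells under 20 spots flagged `low_n`). Lesional/non-lesional
ratios replace a zero denominator with the pseudo-frequency
$100/(n_{\text{spots}}+1)$, flagged.

Severity associations are Spearman rank correlations (average ranks for
ties) with the p-value from the large-sample t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — rank-based because PASI is an ordinal
clinical composite and niche percentages are bounded and skewed. The
**imbalance index** is the z-scored epidermal MAIT percentage minus the
z-scored dermal γδT percentage. z-scoring uses the $n-1$ standard deviation
and is computed *over lesional samples only*: the index is read against
PASI, which exists only for lesional skin, so standardising over a
population that includes HC/NL samples would let their baseline shift the
index's centre arbitrarily.

## Spatial statistics

Spatial weights are binary k-nearest-neighbour graphs (Euclidean, default
k = 6 matching hexagonal Visium packing), symmetrised by union, no
self-edges; distance ties break by spot index so duplicated coordinates are
deterministic. Moran's I uses the standard cross-product form with null
expectation $-1/(N-1)$; a constant field returns `NaN` with a
`constant_field` flag rather than an error, because all-background layers
are routine. Inference is by seeded label permutation with the $+1/+1$
correction, $p = (1 + \#\{|I_\pi - E[I]| \ge |I_{\text{obs}} - E[I]|\}) /
(n_\pi + 1)$, guaranteeing $p \in (0,1]$. By default the pipeline computes
I on the binary indicator field of each subset's labels per sample and
layer; continuous signature scores can be substituted by calling
`morans_i` directly.

## Expression statistics

Differential expression between niche classes uses the two-sided Wilcoxon
rank-sum test per gene (exact enumeration below a combined n of 20,
otherwise the normal approximation with continuity and tie correction, via
`stats::wilcox.test`) with Benjamini–Hochberg adjustment over all tested
genes. The fold change is the difference of group means of log-normalised
expression — the common single-cell convention. The publication filter
keeps $|\log\text{FC}| \ge 0.25$ (inclusive) and adjusted $p < 0.05$
(strict). Enrichment is the upper-tail hypergeometric test against
flat GMT sets, BH-adjusted, ranked by GeneRatio then adjusted p; the
universe defaults to all genes tested for DE. No detection-fraction
pre-filter is applied by default. Group comparisons gate on per-group
Shapiro–Wilk normality at 0.05: t-test vs Wilcoxon for two groups,
ANOVA + Tukey vs Kruskal–Wallis + pairwise Wilcoxon (BH within the post hoc
family) for more; any group under n = 3 forces the non-parametric branch.

## CITE-seq stage

ADT counts are CLR-transformed, by default per cell (the classical
compositional definition; `per_feature` is available since both conventions
circulate in CITE-seq practice), with a +1 pseudo-count for the ubiquitous
zeros. Gating is a declarative hierarchy (`gate_spec`): each gate is a
marker plus a fixed CLR cutoff or a cohort quantile, thresholds computed
once on the full cohort so gating is identical across donors. The shipped
default (CD45 root; TCRγδ for γδT; CD161 ∧ TCR-Vα7.2 for MAIT; CD1d-tet
for iNKT) uses fixed cutoffs placed midway between the negative and
positive marker modes produced by the synthetic generator at its default
effect size — an explicit, editable placeholder for a study-specific
strategy, not a clinical recommendation. Subset frequencies are percentages
of CD45⁺ cells per donor (donors under 50 CD45⁺ cells flagged), and
RNA–protein concordance reuses the Spearman estimator on per-donor pairs.

## The synthetic generator

The generator defines the conditions under which the pipeline is validated.

* **Reference** (`make_reference`): 300 genes × 6 cell types (fibroblast,
  keratinocyte, four T lineages), log-normal baseline (sdlog 1), 20
  exclusive markers per type at 8-fold elevation, plus mild per-type
  log-normal variation (sdlog 0.3) of non-marker expression — real cell
  types differ genome-wide, not only at their markers, and a reference
  whose columns are identical off-marker would be unrealistically
  collinear. The leading markers carry canonical symbols so the shipped
  signatures work on synthetic data unchanged.
* **Sections** (`simulate_section`): hexagonal lattice with unit spacing
  and offset rows; top 30% of rows form the epidermal band. Background
  spots hold 5% total T; planted niche spots add a 0.25 fraction of their
  subset. Counts are negative binomial with mean = depth × mixture
  (depth 5000) and overdispersion φ = 0.5 in the standard UMI
  parameterisation (variance $\mu + \phi\mu^2$; φ = 0 gives Poisson).
* **Cohorts** (`simulate_cohort`): lesional PASI uniform on 2–30; planted
  dermal γδT spot proportion falls linearly 0.15 → 0.03 and epidermal MAIT
  rises 0.03 → 0.20 across that range, with Gaussian jitter (sd 0.02) on
  the proportion scale — the simplest monotone structure that supports
  rank-correlation recovery; HC/NL samples sit at a 0.02 background.
  Negative jittered proportions clip at 0 with a warning. One top-level
  seed fans out to per-section child seeds by fixed offsets.
  `counts = FALSE` returns only the planted per-sample ground truth, which
  is what the replicated severity-recovery calibrations consume — the
  planted links live on the proportion scale, and the statistics under
  test take per-sample summaries.
* **CITE-seq** (`simulate_citeseq`): multinomial subset labels
  (γδT 3%, MAIT 4%, iNKT 1%), ADT counts negative binomial with the
  positive markers of a cell's subset elevated 8-fold. The ADT size
  parameter (8) is deliberately tighter than RNA UMI noise: identity
  markers in real panels are strongly bimodal, and that bimodality is the
  premise of threshold gating. Paired per-cell RNA scores are noisy
  membership indicators.

What the generator does **not** emulate: spot bleed-over and lateral
diffusion, doublet structure, histology-driven layer boundaries (layers are
clean bands), platform batch effects, zero-inflation beyond NB, and any
spatial correlation of the noise. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated generative
model, not robustness to every artefact of real Visium data.

## Validation conditions and problem sizes

The shipped tests and `scripts/acceptance.R` run, per stage: 200 random
NNLS instances (≤ 4 types, ≤ 30 genes) against an exhaustive active-set
oracle; 500-spot sections for deconvolution recovery (MAE ≤ 0.05) and
niche recovery (macro-F1 ≥ 0.90 over the classes present in the ground
truth, with 10% γδT and 10% MAIT planted); 1000 null fields of 100 spots
with 199 permutations for Moran calibration; 200 ground-truth cohorts of
12 lesional samples for severity sign recovery; one 2000-gene, 30 vs 30
DE simulation with 100 genes planted at 1.5-fold (balanced up/down so
library sizes stay comparable, and at expression levels where a 1.5-fold
shift is detectable at that n — the fixture tests the statistic, not
sampling-noise limits); and 200 twelve-donor concordance draws at planted
ρ = 0.9. These sizes keep the whole suite in the low minutes on one CPU
while leaving the Monte-Carlo bands comfortably narrower than the margins
they check.

## Known limitations

* Niche labels are hard assignments; no label uncertainty is propagated
  into the frequency statistics.
* The adaptive T gate is a quantile-with-floor rule; where the true niche
  prevalence in a sample is far from (1 − quantile), gate sensitivity and
  specificity trade off accordingly.
* The deconvolution reference must share gene symbols with the dataset
  (intersection floor 50); no cross-platform harmonisation is attempted.
* Moran's I is a global statistic per sample × layer; local indicators,
  Geary's C and variograms are out of scope.
* The CITE-seq stage performs no background (DSB-style) denoising or
  doublet removal; gates operate on raw CLR values.
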