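# iltcmap

Spot-level mapping of innate-like T-cell (iLTC) niches — γδT, MAIT and iNKT —
in Visium-style spatial transcriptomics of inflamed skin, with the
companion statistics that relate niche organisation to clinical severity,
and a CITE-seq stage for the circulating counterparts of the same subsets.

## Who this is for

Skin immunologists and computational biologists working with spatial
transcriptomics of psoriatic or otherwise inflamed skin who want to ask:
*where* do rare innate-like T-cell programmes sit (epidermis vs dermis), do
lesions carry more of them than non-lesional skin, and does their
layer-specific abundance and spatial patterning track clinical severity
(PASI)? Because Visium spots contain small mixtures of cells, all calls are
**niche-level** (a spot dominated by a subset's transcriptional programme),
not single-cell identifications.

## The method

1. **Deconvolution.** Each spot's depth-normalised expression
   \(y\) (counts per 10k, linear scale) is decomposed against reference
   cell-type profiles \(P\) by non-negative least squares,
   \(\hat x = \arg\min_{x \ge 0}\lVert P x - y\rVert_2\), solved with a
   Lawson–Hanson active set. Because UMI noise is negative binomial
   (variance \(\mu + \phi\mu^2\)), the default fit is iteratively
   reweighted by the fitted noise standard deviation, with \(\phi\)
   moment-estimated from the data. Proportions are
   \(\hat x / \sum_k \hat x_k\).
2. **Niche calling.** A spot passes the T gate when its total T fraction
   reaches its sample's adaptive threshold
   \(\max(Q_{0.80}(\text{T fraction}), 0.05)\) — per-sample, so the gate
   adapts to immune-cell density. Among passing spots the label is the
   subset with the largest within-sample z-scored signature score
   (signatures: TRDC/TRGC1/TRGC2/KLRD1/B2M for γδT; KLRB1/DPP4/CXCR6/IL7R
   for MAIT), provided that z-score is positive.
3. **Frequencies and severity.** Per-sample × layer niche percentages feed
   lesional/non-lesional ratios, Spearman correlations with PASI, and the
   **imbalance index** — z-scored epidermal MAIT percentage minus z-scored
   dermal γδT percentage per lesional sample — summarising the opposing
   layer dynamics in a single number.
4. **Spatial patterning.** Moran's I,
   \(I = \frac{N}{W}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}\), on
   binary k-nearest-neighbour weights (k = 6, the hexagonal Visium packing)
   per sample and layer, with seeded permutation p-values.
5. **Expression statistics.** Wilcoxon rank-sum differential expression
   with Benjamini–Hochberg adjustment (kept when \(|\log\text{FC}| \ge
   0.25\) and adjusted p < 0.05), hypergeometric gene-set enrichment
   against user-supplied GMT sets, and Shapiro–Wilk-gated group
   comparisons (t / Wilcoxon; ANOVA+Tukey / Kruskal–Wallis).
6. **CITE-seq stage.** ADT counts are CLR-normalised per cell,
   subsets gated by explicit threshold hierarchies applied uniformly across
   donors, and per-donor protein-defined frequencies tested for Spearman
   concordance with RNA signature scores.

A synthetic-cohort generator (`make_reference`, `simulate_section`,
`simulate_cohort`, `simulate_citeseq`) plants known cell-type fractions,
niche labels, severity links and subset frequencies, so every stage has a
parameter-recovery test with no external downloads.

## Worked example

Simulate one lesional section with planted niches, deconvolve, call niches
and summarise:

```r
library(iltcmap)

ref <- make_reference(seed = 1)                       # 300 genes x 6 cell types
sec <- simulate_section(ref, n_spots = 400,
  niche_spec = list(epidermis = c(gdT = 0.05, MAIT = 0.12, iNKT = 0.01),
                    dermis    = c(gdT = 0.12, MAIT = 0.03, iNKT = 0.01)),
  sample_id = "PsoL1", group = "L", pasi = 14.5, seed = 42)

fractions <- deconvolve_spots(sec$dataset, ref)
fractions
#> fraction_table: 400 spots x 6 cell types
#>   flags: ok=400
#>   mean proportions:
#>   fibroblast keratinocyte        T_gdT       T_MAIT       T_iNKT       T_conv
#>       0.5462       0.3394       0.0366       0.0263       0.0144       0.0371

log_expr <- log_normalize(sec$dataset$counts)
sigs <- default_signatures()
scores <- sapply(c(gdT = "gdT", MAIT = "MAIT", iNKT = "iNKT"),
                 function(nm) score_signature(log_expr, sigs[[nm]]))
calls <- call_niches(fractions, scores, sec$dataset)
niche_frequencies(calls, sec$dataset)
#>   sample group     layer pasi n_spots pct_gdT pct_MAIT pct_iNKT low_n
#> 1  PsoL1     L    dermis 14.5     280    11.1     4.29     3.21 FALSE
#> 2  PsoL1     L epidermis 14.5     120     7.5    10.83     5.00 FALSE
```

The recovered layer pattern mirrors what was planted: γδT niches dominate
the dermis (11.1% vs the planted 12%), MAIT niches the epidermis (10.8% vs
the planted 12%), with small inflation from background spots near the gate.
The mean deconvolved fractions show the expected fibroblast-dominant dermis
/ keratinocyte epidermis mixture with a total T compartment of ~11%
(background 5% plus the planted niches).

`run_pipeline()` chains QC → deconvolution → calling → frequencies →
severity statistics → DE/enrichment and writes six CSV reports
(`niche_calls.csv`, `sample_summary.csv`, `severity_stats.csv`,
`de_table.csv`, `enrichment.csv`, `cite_summary.csv`), byte-identically for
a fixed seed. A thin command-line front end is shipped in
`inst/cli/iltc.R` (`simulate`, `run`, `cite` subcommands).

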