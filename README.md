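# RecurNet

Differential co-expression network analysis and survival validation for
tumor-recurrence biomarkers.

## The problem

Post-surgical recurrence is the main obstacle to long-term survival in
early-stage hepatocellular carcinoma, and peripheral-blood expression
profiles offer a non-invasive window on it. The discovery design this
package implements splits patients into a recurrence group (event within
12 months of surgery) and a non-recurrence group (event-free for at
least 36 months), then asks which genes distinguish the groups not only
in *mean expression* but in *network wiring* — and whether the resulting
candidates actually predict recurrence-free survival. RecurNet is for
computational biologists who want that whole chain as tested, scriptable
R, with a synthetic-cohort generator so every stage can be exercised
without access to patient data.

## The method

1. **Moderated differential expression.** A random-variance-model (RVM)
   t-test shares variance information across genes: gene precisions get
   an inverse-gamma prior fitted by maximum likelihood (`a*b*s² ~
   F(d, 2a)`), the moderated variance is `(d·s² + 2/b)/(d + 2a)`, and
   the test gains `2a` degrees of freedom — workable even at 3 vs 3
   samples. Genes pass at `p < 0.05` and Benjamini–Hochberg
   `FDR < 10%`.
2. **Enrichment.** Categories are scored with the enrichment ratio
   `Re = (nf/n)/(Nf/N)` plus two-sided Fisher exact and chi-square
   tests, separately for up- and down-regulated sets; `LgP = log10(p)`.
3. **Differential connectivity.** Per-group Pearson co-expression
   networks over the DEG set (edges: `p < 0.05` and `|r| ≥ 0.7`),
   k-core decomposition, and per-gene
   `DiffK(i) = K1(i) − K2(i)` with `Kj(i) = kj(i)/max(kj)` — genes more
   connected in the recurrence network rank first. A label-permutation
   empirical null for DiffK is available.
4. **Survival validation.** Top-DiffK markers are dichotomized at the
   Youden-optimal ROC cutoff and validated with Kaplan–Meier curves,
   log-rank tests, and univariate/multivariate Cox proportional-hazards
   models; contingency tests, nonparametric group comparisons, Spearman
   correlation and IHC quantification indices (AIOD, LI) round out the
   toolkit.

See `vignettes/recurnet-methods.Rmd` for the models, assumptions, and
every configurable threshold.

## Worked example

```r
library(RecurNet)

cfg <- simulationConfig(seed = 42)           # 2000 genes x 80 patients
run <- runPipeline(pipelineConfig(simulation = cfg, seed = 42),
                   outDir = "recurnet_out")
print(run)
#> RecurNet run: 192 up / 193 down DEGs
#> top DiffK genes: G00301, G00302, G00303, G00304, G00305

head(run$metrics[, c("gene_id", "k1", "k2", "K1", "K2", "diffK")], 3)
#>   gene_id k1 k2 K1 K2 diffK
#> 1  G00301 29  0  1  0     1
#> 2  G00302 29  0  1  0     1
#> 3  G00303 29  0  1  0     1

v <- run$report$markerValidation[[1]]
```

The synthetic cohort plants a 30-gene module co-expressed at r = 0.9
only among recurrence patients; its three hub genes (G00301–G00303)
come out on top of the DiffK ranking with `diffK = 1` (degree 29 in the
recurrence network, 0 in the non-recurrence network). Validation of the
top marker against the simulated recurrence-free survival prints:

```
top marker G00301: AUC 0.900, cutoff 9.14
pct high: recurrence 84.6%, non-recurrence 5.6%
log-rank p = 5.8e-08; Cox HR 12.41 (95% CI 4.11-37.53)
```

i.e. 84.6% of recurrence patients are high-expressors at the ROC-derived
cutoff, and high expression carries a large recurrence hazard — the
pattern a genuine blood-borne recurrence marker would show. All stage
tables (DE, enrichment, edge lists, node metrics, KM steps), a JSON
report and an MD5 manifest land in `recurnet_out/`.

A shell entry point with `simulate` / `run` subcommands and a YAML
config lives at `inst/scripts/recurnet.R`.

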