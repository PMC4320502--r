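# leukomet — leukocyte metagene analysis of bulk tissue transcriptomes

Bulk expression profiles of inflamed tissue (for example synovial biopsies
from spondylarthropathy patients) mix transcripts from resident stromal
cells with those of infiltrating leukocytes. `leukomet` answers "which
immune cell types are over-represented in the disease group?" using only the
bulk profiles plus a reference of purified leukocyte populations. It is
aimed at transcriptomics analysts who want a transparent, marker-based
infiltration readout rather than a full deconvolution model.

The pipeline has three statistical pieces:

1. **Marker panels via nearest shrunken centroids (PAM).** On the purified
   reference with classes k, class centroids x̄_ik, overall centroid x̄_i,
   pooled within-class SD s_i (denominator n−K), s0 = median(s_i), and
   m_k = sqrt(1/n_k − 1/n):

       d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s0))

   The top 25 genes per cell type by signed d_ik (disjoint across types by
   greedy round-robin) form that type's **metagene**; 6 leukocyte types give
   a 150-gene classifier. Soft-thresholding and the shrunken-centroid
   discriminant are available for classification (`shrink()`, `classify()`).

2. **Metagene score.** After per-dataset standardization of each gene to
   mean 0, SD 1, a sample's score for cell type c is the mean z-score of the
   panel genes: score(s, c) = (1/n_P) Σ_{i∈P_c} x_is.

3. **Differential infiltration.** Per cell type, a two-sided two-sample
   t-test (pooled-variance Student by default, Welch optional) on the scores,
   disease − control, significant at p ≤ 0.05 (BH-adjusted q-values emitted
   as supplementary output).

A synthetic-data module (`sim_config()`, `simulate_reference()`,
`simulate_cohort()`) generates purified references with planted markers and
bulk cohorts as Dirichlet-weighted convex mixtures of cell-type signatures
plus stroma, so every stage is testable without downloads.

## Worked example

```r
library(leukomet)

# disease shifts DC and CD4+ T fractions up by 0.15 each, displacing stroma
cfg <- sim_config(fraction_shift = c(DC = 0.15, CD4T = 0.15))
res <- run_pipeline(cfg, seed = 42)   # reference -> markers -> cohort -> tests

res$panels
#> Marker panels (6 classes, k = 25)
#>   Monocyte [25]: g0367, g0370, g0410, g0321, g0024, ...
#>   DC [25]: g0299, g0114, g0004, g0226, g0324, ...
#>   ...

print(res$comparison[, c("cell_type", "diff", "t", "p", "significant")],
      digits = 3)
#>   cell_type    diff      t        p significant
#> 1  Monocyte -0.1242 -0.983 0.343431       FALSE
#> 2        DC  0.3250  2.448 0.029343        TRUE
#> 3        NK  0.0214  0.333 0.744468       FALSE
#> 4      CD4T  0.5734  5.179 0.000177        TRUE
#> 5      CD8T  0.0909  0.850 0.410796       FALSE
#> 6         B  0.0663  0.693 0.500531       FALSE
```

`diff` is the disease − control difference in mean metagene score (units:
average z-score of the 25 panel genes), `t` the pooled-variance t statistic
on 13 degrees of freedom. The two cell types whose fractions were actually
shifted — and only those — are flagged at p ≤ 0.05: the DC score is 0.33
z-units higher in disease (p = 0.029), CD4+ T 0.57 higher (p = 2e-4).
`res$recovery` shows the panel validation: each metagene scores strictly
highest in its own purified population.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
stand-ins and write tables under `results/`:

| script | what it does |
|---|---|
| `01_build_reference.R` | purified reference, NSC fit, 25-gene metagenes (GMT + model JSON) |
| `02_validate_metagenes.R` | reference scores and self-recovery table |
| `03_mouse_cohort.R` | 4 vs 4 cohort with a broad 4-cell-type influx |
| `04_human_cohort.R` | 7 vs 8 cohort with selective DC/CD4+ T influx |
| `05_operating_characteristics.R` | type-I error, power, power-vs-shift curve |

Run them in order: `for f in analysis/0*.R; do Rscript "$f"; done`

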