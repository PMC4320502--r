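---
title: "Leukocyte metagenes: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leukocyte metagenes: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukomet)
```

## The problem

Bulk tissue expression profiles — say synovial biopsies from patients with
inflammatory joint disease — mix transcripts from resident (stromal) cells
and from whatever leukocytes have infiltrated. `leukomet` estimates *which*
immune cell types are over-represented in a disease group relative to
controls, using nothing but the bulk profiles plus a reference of purified
leukocyte populations. The approach is deliberately simple and transparent:
learn a small marker panel ("metagene") per cell type from the purified
reference, summarize each bulk sample by the average z-score of each panel,
and compare those summaries between groups.

## Marker selection: nearest shrunken centroids

Markers are chosen with the classical nearest-shrunken-centroid (NSC,
PAM-style) statistics. With classes $k = 1..K$, class sizes $n_k$,
$n = \sum_k n_k$, class centroids $\bar x_{ik}$ and overall centroid
$\bar x_i$ for gene $i$:

$$ d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k\,(s_i + s_0)}, \qquad
   m_k = \sqrt{1/n_k - 1/n}, $$

where $s_i$ is the pooled within-class standard deviation (denominator
$n-K$) and $s_0$ is the median of the $s_i$, a stabilizer for low-variance
genes. Soft-thresholding
$d'_{ik} = \mathrm{sign}(d_{ik})\,\max(|d_{ik}|-\Delta,\,0)$ and the
discriminant
$\delta_k(x) = \sum_i (x_i-\bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$ complete
the classifier (`shrink()`, `classify()`).

Design choices where the procedure was genuinely open:

* **Ranking.** The top-$k$ panel of a class takes genes by *signed* $d_{ik}$
  descending: a marker must be elevated in its own class, not merely
  discriminative. Ranking by $|d_{ik}|$ is available via
  `select_markers(..., rank = "abs")` but is not the default, because a
  "marker" that is specifically *absent* in its class would corrupt the
  infiltration interpretation of the score.
* **Disjointness.** Panels are made disjoint by greedy round-robin: in class
  order, each class claims its best still-unclaimed gene, for $k$ rounds.
  This makes $K$ panels of size $k$ contain exactly $kK$ distinct genes
  (6 classes at $k=25$ give the 150-gene classifier) and is deterministic.
* **Ties** in ranking break by lexicographic gene ID; ties in the
  discriminant break by class order. Both are documented, reproducible
  conventions rather than claims about any particular historical run.
* **No cross-validated threshold path.** The shrinkage $\Delta$ defaults to
  0; panel size is controlled directly by $k$ (default 25). Cross-validation
  over $\Delta$ is out of scope because the analysis fixes a panel size
  rather than a shrinkage level.
* Class priors $\pi_k$ default to empirical frequencies. Degenerate-small
  designs (2 replicates per class, $n-K = 6$) are supported and tested.

## The metagene score

Each dataset is standardized per gene to mean 0, SD 1 (sample SD, $n-1$
denominator) across *all* its samples, controls and disease together
(`standardize_genes()`). The metagene score of sample $s$ for cell type $c$
is then

$$ \mathrm{score}(s,c) = \frac{1}{n_P}\sum_{i\in P_c} x_{is}, $$

the mean z-score of the panel genes. Consequences worth knowing:

* Scores are **relative within a dataset** — column means are 0 by
  construction, so a score says "above/below this cohort's average", never
  an absolute cell fraction. Scores from different datasets are not
  comparable; `write_scores()` records a dataset ID to discourage silent
  cross-dataset comparison.
* Zero-variance genes standardize to all-zero rows (with a warning) and thus
  contribute nothing to a score — the neutral choice.
* Panel genes missing from a target dataset (cross-platform or cross-species
  loss after the user-supplied probe/ortholog mapping) are dropped by
  default and the effective panel size is recorded; `missing = "error"`
  makes full coverage mandatory. An entirely absent panel is always an
  error.
* Probe-level data collapse to one row per gene by keeping the probe with
  the highest mean across samples; ties keep the earlier probe in input
  order.

Panel validity is checked by *self-recovery* (`self_recovery()`): on the
purified reference, each cell type's metagene score must be strictly highest
in its own population, with the margin to the best competitor reported.

## Group comparison

`compare_groups()` runs a two-sided two-sample t-test per cell type,
reporting the difference and t as disease − control (positive = increased
infiltration), with significance at $p \le 0.05$. The default is the
pooled-variance Student test (df $n_1+n_2-2$); Welch is a flag. No
multiple-testing correction is applied to the significance call — the
analysis reports per-cell-type decisions — but a Benjamini–Hochberg column
(`bh_q`) is emitted alongside as supplementary output.

## What the synthetic generator emulates

`sim_config()` + `simulate_reference()` + `simulate_cohort()` generate data
with the statistical structure the analysis assumes:

* **Reference**: 6 leukocyte classes × 2 replicates, 500 genes, 30 disjoint
  true markers per class elevated by `marker_effect` (3) × `noise_sd` (1)
  on a log-like scale, i.i.d. Gaussian noise. The layout mirrors a purified
  leukocyte compendium with duplicate arrays per sorted population.
* **Cohorts**: each bulk sample is a convex mixture
  $\sum_c f_c\,\mathrm{sig}_c + f_{stroma}\,\mathrm{stroma} + \varepsilon$.
  Per-sample fractions are Dirichlet-distributed around group means
  (concentration 50, mild biological variability); control tissue is 50%
  stromal with the remainder split equally across the 6 leukocyte types;
  disease shifts named fractions additively (e.g. DC and CD4+ T +0.15),
  displacing stroma. If shifts exhaust the stromal reserve, stroma clips to
  0 and the leukocyte fractions renormalize; a negative fraction is an
  error. Cohort sizes default to 7 control vs 8 disease (the human-style
  layout); 4 vs 4 reproduces the small-animal layout.
* Linear mixing on the log-like scale is the default because it is the
  simplest generative model under which the z-score-average is a consistent
  infiltration readout (the score is then linear in the true fraction);
  `mixing = "lognormal"` mixes on the anti-log scale instead, which is
  physically closer to transcript counts but makes the score an
  approximation. The generator is a testing device, not a claim about how
  any real biopsy arises.

What it does **not** emulate: probe-level artifacts, batch effects between
series, correlated gene-gene noise, compositional distortions of
normalization, or cell types absent from the reference. Passing tests on
this generator show the pipeline recovers the structure it assumes; they do
not certify performance on real arrays, where marker cross-reactivity and
platform mapping loss are the dominant risks.

## Numerical and procedural conventions

* Sample SD ($n-1$) everywhere; standardization tolerance 1e-10;
  standardization is idempotent to 1e-8 on non-degenerate rows.
* A matrix is accepted for scoring only if every gene row mean is within
  1e-6 of 0, catching unstandardized input early.
* TSV I/O writes 15 significant digits, so round trips preserve values well
  past 12 significant digits; malformed files fail with the offending line
  and cell named.
* All simulation is driven by a single seeded RNG stream: identical seed and
  configuration give bit-identical datasets.

## Problem sizes and operating characteristics

The bundled analyses and tests run the generator at its default sizes
(500 genes; 12 reference samples; 15- or 8-sample cohorts) and use 60–100
pipeline replicates for power summaries, 400–2000 for type-I error — sizes
chosen so a full rerun of everything stays in the minutes range on one CPU
while keeping Monte-Carlo error small relative to the effects examined.
Measured on these conditions (see `analysis/05_operating_characteristics.R`,
which recomputes them): per-cell-type type-I error sits at the nominal 5%
within Monte-Carlo error; DC detection power rises from ~0.2 at a +0.05
fraction shift to ~0.97 at +0.20; under the DC/CD4+ T +0.15 condition the
per-type power is ~0.85. Note a structural ceiling on the *joint* event
"both shifted types flagged and both null types spared": with two true
nulls tested at $\alpha = 0.05$, its probability cannot exceed
$0.95^2 \approx 0.90$ even at perfect power, and at these sample sizes and
fraction variability it lands near 0.7.

## Known limitations

* The score is relative and compositional: a large influx of one cell type
  mechanically depresses the standardized scores of others in the same
  dataset.
* Closely related populations (CD4+ vs CD8+ T cells) share markers'
  correlated expression; disjoint panels mitigate but do not remove
  cross-specificity.
* With 2 replicates per reference class, the pooled SD rests on 6 degrees of
  freedom; marker rankings are correspondingly noisy, which is why panel
  recovery is validated in distribution (many seeds) rather than per run.
* No covariate adjustment, nonparametric alternatives, or mixed models; the
  comparison layer is deliberately the plain two-sample t-test.
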