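# irgpair

Prognostic modelling of cutaneous melanoma (and similar cohorts) with
**immune-related gene pairs** (IRGPs): rank-based, within-sample binary
features that are immune to normalisation and platform differences, combined
into a weighted risk score by penalised Cox regression.

## The problem and the model

Absolute expression values rarely transfer between RNA-seq and microarray
cohorts. The gene-pair approach sidesteps this: for a pair of immune-related
genes (i, j), the feature is the indicator

```
s_ij(sample) = 1  if  x_i > x_j   (strictly, within the sample)
             = 0  otherwise (including ties)
```

which depends only on the *ordering* of the two genes inside one sample and
is therefore invariant to any strictly increasing transform of the
expression scale. The pipeline is:

1. **Candidate construction** — restrict to immune-related genes present in
   every cohort, keep genes with median absolute deviation (MAD) > 0.5,
   enumerate all pairs, and drop pairs whose indicator is constant in any
   cohort.
2. **Screening** — a univariate log-rank (Cox score) test per pair against
   overall survival, retaining pairs with p < 0.001.
3. **Selection** — LASSO-penalised Cox regression with 10-fold
   cross-validation (deviance-minimising lambda) yields a sparse signature
   of pairs with coefficients β.
4. **Scoring** — the gene-pair index of a sample is
   `IRGPI = Σ_pairs β_ij · s_ij`; patients are split into low/high risk at
   the Youden-optimal threshold of the time-dependent ROC curve at 5 years
   (cumulative/dynamic definition, IPCW censoring weights).
5. **Validation** — Kaplan-Meier curves and the log-rank test between risk
   groups, uni-/multivariate Cox models of the continuous score, Wilcoxon
   comparisons of immune-cell fractions between groups, and hypergeometric /
   preranked-GSEA enrichment statistics.

The package ships a published 41-pair melanoma signature
(`default_signature()`) as a ready-to-use scoring asset, and a synthetic
cohort generator (`simulate_cohort()`) so every stage is testable fully
offline.

## Worked example

Train and validate on a synthetic cohort with five survival-driving planted
pairs (n = 500, 30% censoring):

```r
library(irgpair)
sim <- simulate_cohort(n_genes = 60, n_samples = 500, n_planted = 5, seed = 20)
tr  <- run_train(sim$expr, sim$clinical, rownames(sim$expr), irgp_config(seed = 20))
tr$report
#> $genes_in             [1] 60
#> $genes_after_mad      [1] 22
#> $pairs_built          [1] 231
#> $pairs_after_constant [1] 217
#> $screen_survivors     [1] 30
#> $selected_pairs       [1] 15
```

The funnel mirrors the published analysis: genes in, genes passing the MAD
filter, pairs enumerated, pairs surviving the constancy filter, screen
survivors, and the final signature size. All five planted pairs are among
the 15 selected. Validation at a 5.7-time-unit horizon (the cohort median):

```r
val <- run_validate(sim$expr, sim$clinical, tr$signature,
                    irgp_config(horizon = 5.7, seed = 20))
val$report
#> cutoff = 2.151, tdROC AUC = 0.835
#> n_low = 266, n_high = 234
#> log-rank chi2 = 209.1, p = 2.2e-47
val$cox_uni$table
#>    term  coef    hr ci_low ci_high        p
#>   irgpi 1.137 3.117  2.735   3.554  6.8e-65
```

High-risk patients (score above the cutoff) have roughly 3-fold the hazard
per unit of score and a clearly separated Kaplan-Meier curve.

Scoring with the packaged 41-pair signature works on any expression matrix
containing its 62 genes:

```r
sig <- default_signature()        # 41 pairs, coefficients sum to -0.851
scores <- compute_irgpi(expr_matrix, sig)
risk   <- assign_groups(scores, cutoff = -0.245)
```

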