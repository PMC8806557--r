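---
title: "Immune gene-pair prognostic signatures: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune gene-pair prognostic signatures: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpair)
```

## The model

A gene-pair signature replaces absolute expression values with within-sample
orderings. For an ordered pair of genes $(g_1, g_2)$ the feature of sample
$s$ is the indicator $\mathbb{1}[x_{g_1,s} > x_{g_2,s}]$, with ties scoring
0. A signature is a set of such pairs with Cox-derived weights $\beta_k$,
and the per-patient risk score (the gene-pair index, IRGPI) is

$$\mathrm{IRGPI}(s) = \sum_k \beta_k \,\mathbb{1}[x_{g_{1k},s} > x_{g_{2k},s}].$$

Two structural properties follow immediately and are enforced as tests:
the score is invariant to any strictly increasing transform of the
expression values (so log-transformation, quantile normalisation or
platform rescaling cannot change it), and it is additive over any partition
of the signature's rows. The pair direction is meaningful: $(A, B)$ and
$(B, A)$ are different features, so the printed direction of a signature is
used verbatim and never canonically reordered. During *candidate
construction*, by contrast, unordered pairs in lexicographic direction are
enumerated — the two conventions differ only by the sign convention of the
fitted coefficient.

Survival follows a proportional-hazards model in the selected features. The
training funnel is: immune-gene intersection across cohorts → per-gene MAD
filter (> 0.5, unscaled) → exhaustive pair enumeration → removal of pairs
constant in any cohort → univariate log-rank screen (p < 0.001) →
LASSO-Cox with 10-fold cross-validation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mad_threshold` | 0.5 | per-gene variability floor (expression units, unscaled MAD) |
| `mad_scale` | 1.0 | set 1.4826 for normal-consistent MAD; retained sets grow monotonically |
| `screen_p` | 0.001 | univariate score-test threshold per pair |
| `folds` | 10 | CV folds for the penalised Cox fit |
| `min_freq` | 0 | minority-frequency floor for pair retention; 0 removes only strictly constant pairs |
| `horizon` | 5 years (1825 days / 60 months by `time_unit`) | tdROC evaluation time for the cutoff |
| `n_perm`, `gsea_fdr` | 10000, 0.002 | GSEA permutations and significance threshold |

All of these live in `irgp_config()`; nothing numeric is hard-coded in the
stage logic. One top-level `seed` derives the per-stage seeds by fixed
offsets, so stages are independently reproducible and a rerun with the same
config is byte-identical.

## Statistical components and their conventions

**Log-rank / screen.** The screen computes the classic one-degree-of-freedom
log-rank statistic from hypergeometric moments at each distinct event time,
vectorised over all candidate pairs at once; it equals the Cox score test
for a binary covariate with Breslow ties (verified numerically against
`survival::survdiff` in the tests). The screen uses the score p-value
rather than a Wald p: the two are asymptotically equivalent, and the score
test is exact under the null ordering logic and cheaper at scale.

**Cox fits.** `survival::coxph` with Efron tie handling by default — the
least-biased of the common tie conventions — and 95% Wald intervals
throughout. Non-convergence (e.g. separation) is reported as a flag on the
result, not an exception, so pipeline runs fail soft.

**LASSO selection.** `glmnet::cv.glmnet` on the partial-likelihood deviance
over its standard geometric lambda grid (100 points, 4 decades). We select
`lambda.min`, not `lambda.1se`: the published signature keeps 41 of 2,215
screened pairs, a density far more consistent with the deviance-minimising
choice than with the extra-parsimonious one. Folds are stratified by event
status so every fold carries events — plain random folds are available via
`stratify_folds = FALSE`. Correlated or duplicated predictors are handled
by the LASSO itself (coefficient mass is shared; the attainable deviance is
unchanged, a property the tests check); no separate similarity
deduplication pass is applied. Penalised coefficients are reported by
default; `refit = TRUE` refits an unpenalised Cox model on the selected
pairs — the small magnitudes typical of published pair signatures are
consistent with shrinkage, hence the default.

**Time-dependent ROC.** Cumulative/dynamic definition at the horizon:
cases have an observed event by then, controls are still under observation
beyond it, and subjects censored earlier contribute through
inverse-probability-of-censoring weights from the Kaplan-Meier estimate of
the censoring distribution. This IPCW estimator is deterministic and
reduces exactly to the empirical binary ROC when there is no censoring
(tested against a rank-sum AUC). A nearest-neighbour-smoothed estimator is
a common alternative; it introduces a bandwidth choice and was deliberately
not used. The cutoff maximises Youden's J, with ties broken toward the
smallest threshold so the choice is deterministic; "optimal cutoff" alone
underdetermines a criterion, and Youden is the conventional reading. Group
assignment is `score > cutoff → high`, chosen so that with a negative
cutoff and a risk-increasing score the high-risk group is the
worse-survival group.

**Enrichment.** The preranked GSEA enrichment score is the weighted
Kolmogorov–Smirnov running sum (hit increments $\propto |s|^{weight}$,
uniform miss decrements, maximum deviation retained with its sign), with
gene-label permutations preserving set size — the scheme that operates on a
bare ranked list. p-values compare against same-sign permuted scores with
the +1 continuity correction; NES divides by the mean magnitude of
same-sign permuted scores. Over-representation uses the one-sided
hypergeometric tail; all multiplicity adjustment is Benjamini–Hochberg.
Ranking between risk groups uses `log2((mean_high + c)/(mean_low + c))`
with a tiny pseudo-count on linear-scale data, or the plain mean difference
when the data are declared log-scale.

**Immune-cell fractions.** Deconvolution output (e.g. the standard 22-type
table) is consumed, never computed: fractions are renormalised to the
simplex and compared between risk groups with two-sided Wilcoxon rank-sum
tests (exact when sample sizes permit and there are no ties).

## The synthetic-data generator

`generate_expression()` draws gene baselines $\mu_g \sim U(2, 12)$ (log2-
intensity-like) and noise scales $\sigma_g$ log-normal with median 0.5, so
per-gene MADs straddle the 0.5 filter the way a mixed
informative/uninformative panel would. `plant_signature()` picks disjoint
pairs among filter-passing genes whose baselines are close on the scale of
their combined noise — pairs whose indicators actually flip between
samples — and assigns alternating ±1 coefficients. `generate_survival()`
draws event times from an exponential-baseline Cox model driven by the
planted IRGPI, with independent Uniform(0, $T_c$) censoring, $T_c$ tuned by
bisection to hit the requested censoring fraction within ±0.02 (30%
default, a typical cohort value). `generate_fractions()` draws Dirichlet
cell fractions with concentration multiplied by $e^{\mathrm{effect}}$ for
shifted types in one risk group.

What the generator does **not** emulate: negative-binomial count noise,
batch effects, gene–gene correlation beyond the planted pairs, informative
censoring, and covariate-linked risk (age, stage). Passing tests therefore
demonstrate correctness of the machinery and recoverability under the
stated generative model — not clinical performance on real cohorts.

The end-to-end recovery study used in the tests runs 25 cohorts of n = 500
with 60 genes and 5 planted pairs (|β| = 1, 30% censoring); the pipeline
recovers all planted pairs in every replicate with about 7 spurious pairs
on average — spurious selections are overwhelmingly pairs sharing a gene
with a planted pair, which the LASSO keeps because they are genuinely
correlated with risk.

## Numerical and degenerate-input choices

* Ties in expression score 0 in both pair directions (the literal "greater
  than" rule); antisymmetry $s(A,B) + s(B,A) = 1$ therefore holds only for
  tie-free data.
* Duplicate gene rows (or probes mapping to one symbol) are averaged — one
  rule, one code path; rows with missing values are dropped, not imputed,
  because a rank indicator on imputed values would be a fabricated ordering.
* Pairs constant in the aligned training cohort are skipped by the screen
  (they carry no information and would make the score test degenerate).
* `signature_profile()` realises a requested indicator pattern by treating
  the orderings as a DAG and assigning longest-path depths; cyclic requests
  are impossible by construction and raise an error.
* The packaged 41-pair asset is stored as printed, to the printed precision;
  its scoring-side checksum (the all-indicators-on score, −0.851) is
  asserted against an independent parse in the tests.
* Whether training expression is log-transformed is deliberately left to
  the user: pair indicators are invariant to the choice, so the pipeline
  never transforms data on its own.

## Problem sizes in the shipped tests

Simulated checks use cohorts of 200–2000 samples and 20–60 genes: large
enough that asymptotic recovery statements (Cox coefficient recovery within
0.1 of ln 2 at n = 1000, hazard-ratio recovery within 0.15 at n = 2000,
null tdROC AUC within 0.05 of 0.5 at n = 500) hold with margin, small
enough that the whole suite runs in well under a minute apart from the
25-replicate recovery study.

## Known limitations

* The cutoff derived on a cohort is optimised in-sample; applying it to the
  same cohort's log-rank test inflates significance slightly. Validation on
  an independent cohort (supported via a fixed `cutoff`) is the honest use.
* The IPCW tdROC assumes censoring independent of the marker; under
  marker-dependent censoring a covariate-adjusted censoring model would be
  needed.
* `allow_missing` scoring drops pairs without renormalising, changing the
  score scale; any fixed cutoff must then be reconsidered — hence missing
  genes are an error by default.
* GSEA with gene-label permutation tests a different null than phenotype
  permutation; enrichment direction relative to the high-vs-low ranking is
  reported as the signed ES and left to interpretation.
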