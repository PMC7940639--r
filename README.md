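# riskclust

Characterising, identifying and clustering diseases by their fitted
associations with common risk factors.

## The problem

Large hospital-linked cohorts make it possible to ask whether easily
measured risk factors — BMI, height, systolic blood pressure, smoking,
alcohol, walking pace, diabetes — carry enough information to
*characterise* a disease: to tell diseases apart, to match the same
disease across sexes, and to group diseases that plausibly share
aetiological pathways.  `riskclust` implements that analysis as a tested,
reusable pipeline for epidemiologists and biostatisticians, together with
a seeded synthetic-cohort generator that plants known risk-profile
structure so every stage can be validated against ground truth.

## The method

For each disease *d* and sex, a proportional hazards model is fitted on
the **age timescale** with left truncation at study entry, stratification
by year of birth, and right censoring at the administrative end of
follow-up or at a competing cancer event:

    h(t | x) = h0,s(t) · exp(βᵀx)

The maximum-likelihood estimate is treated as a multivariate normal,
μ̂ ~ N(μ, Σ).  Diseases pass a statistical inclusion cascade (≥ 50 cases;
a covariance eigenvalue screen at 2.5 SD; a Bonferroni-adjusted
multivariate χ² significance test μ̂ᵀΣ⁻¹μ̂; an FDR-adjusted global
Schoenfeld proportional-hazards test; presence in both sexes).
Marginalisation — taking the rows and columns of μ̂ and Σ for a parameter
subset — reduces each disease to six strong comparison parameters (BMI,
height, SBP, slow walking, regular drinking, current smoking) while
retaining the full multiple adjustment.

Two diseases are compared by the equality test

    (μ̂₁ − μ̂₂)ᵀ (Σ₁ + Σ₂)⁻¹ (μ̂₁ − μ̂₂) ~ χ²(p)

and related by the Bhattacharyya distance between their parameter
distributions,

    D_B = ⅛ (μ₁−μ₂)ᵀ Σ̄⁻¹ (μ₁−μ₂) + ½ log( det Σ̄ / √(det Σ₁ det Σ₂) ),
    Σ̄ = (Σ₁+Σ₂)/2,

which discounts differences that lie within estimation uncertainty.  The
nearest entry by D_B identifies each disease's partner (ideally its own
opposite-sex counterpart); Ward.D2 hierarchical clustering of the D_B
matrix groups diseases, with the cluster count chosen by the elbow of the
within-cluster homogeneity statistic and the smallest N whose homogeneity
p-value exceeds 0.05 also reported.  Clustering stability across
sensitivity reruns (prior-disease exclusion, tertile recoding) is
quantified by the preserved-pair overlap p_AB = n_AB / min(n_A, n_B).

## Worked example

```r
library(riskclust)
run <- run_pipeline(run_config(
  seed = 5, n_participants = 8000, n_diseases = 10, n_clusters = 3,
  profile_args = list(rate_range = c(1e-2, 1.6e-2),
                      center_sd = 0.8, min_cluster_sep = 2.0),
  k_range = 1:10, exclude_prior_rerun = TRUE))
print(run)
```

```
riskclust pipeline run (seed 5 )
  cohort: 8000 participants, 10 diseases; 10 in the unisex set
  identification: top-1 100.0%, top-1 100.0%
  sex differences: 0/10 significant (0.0%); without BMI 0 (0.0%)
  clustering: selected k = 3 ; smallest non-significant N = NA ; ARI vs planted clusters = 1
  sensitivity exclude_prior: p_AB = 1.000 (0 sensitive entries)
```

Reading the output: all 10 synthetic diseases survived the inclusion
cascade in both sexes ("unisex set"); every disease's nearest entry in
Bhattacharyya distance was its own opposite-sex counterpart (top-1
100%); no disease showed a significant male–female difference in its
comparison parameters (none was planted); the elbow criterion selected
k = 3 clusters, exactly recovering the 3 planted profile clusters
(adjusted Rand index 1); and refitting with prior same-cluster disease
excluded left every clustered pair together (p_AB = 1).  At this small
cohort size no cut in `k_range` reaches a homogeneity p-value above 0.05,
so the smallest non-significant N is reported as `NA`.

Individual stages are available as plain functions returning classed
objects with `print`/`summary`/`coef`/`plot` methods: `simulate_cohort()`,
`fit_disease_models()`, `run_selection()`, `marginalise()`,
`equality_test()`, `sex_difference_scan()`, `bhattacharyya_matrix()`,
`identify_partners()`, `hierarchical_cluster()`, `select_k()`,
`compare_clusterings()`.  A thin command-line wrapper lives at
`inst/scripts/riskclust.R`.  See the methods vignette
(`vignettes/methods.Rmd`) for the model, its assumptions, and all design
choices.

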