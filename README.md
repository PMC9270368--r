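# morphoverlap

Quantifies how much the morphologies of two cryptic species overlap in
sympatry, and how much of that overlap is carried by hybrids — the analysis
pipeline built around the Iberian serotine bats *Eptesicus serotinus* and
*E. isabellinus*, whose contact zone hosts molecularly confirmed hybrids.
It is written for evolutionary biologists and morphometricians who want the
full protocol (trait validation, group statistics, PCA summaries, dual
classification engines, overlap arithmetic) as tested, reusable,
tidyverse-style functions.

## The statistic at the core

Every sympatric individual is classified into one of the two species from
its measurements by two independent engines:

* **DFA** — stepwise discriminant-variable selection by Wilks'
  Λ = |W|/|T| (entry/removal at partial F = 3.84/2.71), then quadratic
  discriminant classification with leave-one-out cross-validation on the
  selected raw variables;
* **SVM** — one-vs-rest radial-kernel support vector machines on retained
  PCA scores, over γ ∈ {0.1, 1, 10, 100, 1000} × 20 stochastic restarts,
  combined by a *single-claim* rule: an individual is correct only if
  exactly one class ensemble claims it and the claim matches the molecular
  label.

Each engine runs on morphometry (7 wing/dentition variables, mm) and colour
(6 CIELAB variables), with and without hybrids. Per cell,

    overlap              = 100 − global correct-classification rate (with hybrids)
    hybrid contribution  = 100 × misclassified hybrids / all misclassified

and the four cells are aggregated as mean ± sample sd, with Kruskal–Wallis
(tie-corrected) and one-way ANOVA comparing the 16 per-species rates by
species and the contributions by trait set.

Supporting machinery includes a synthetic five-group cohort generator
calibrated to the published group medians and ranges (truncated-normal
margins, correlated wing variables, a hybrid-intermediacy dial), Box's M,
permutation MANOVA on Euclidean distances, Fisher's LSD / Tukey HSD post
hocs, and correlation-matrix PCA with Kaiser retention and Cronbach's α.

## Worked example

```r
library(morphoverlap)

tab   <- simulate_cohort(cohort_spec(), seed = 1)   # 126 bats, 5 groups
study <- run_overlap_study(tab, svm = svm_config(seed = 1))
study
#> Overlap report (engine x trait-set grid):
#> # A tibble: 4 × 6
#>   trait_set   engine rate_global rate_global_no_hybrids overlap
#>   <chr>       <chr>        <dbl>                  <dbl>   <dbl>
#> 1 morphometry DFA           68.3                   57.7   31.7
#> 2 morphometry SVM           95                     98.1    5
#> 3 colour      DFA           81.7                   76.9   18.3
#> 4 colour      SVM           98.3                   98.1    1.67
#> # ℹ 1 more variable: hybrid_contribution <dbl>
#>
#> Aggregates (mean +/- sample sd):
#> # A tibble: 4 × 4
#>   quantity                         mean    sd     n
#> 1 overlap                          14.2  13.7     4
#> 2 hybrid_contribution              63.8  35.1     4
#> 3 hybrid_contribution_morphometry  41.2  36.0     2
#> 4 hybrid_contribution_colour       86.4  19.3     2
```

Reading it: on this synthetic cohort the DFA leaves 31.7% of sympatric bats
morphometrically unassignable to their molecular species, the SVM ensemble
only 5%, and on average 63.8% of the misclassified individuals are hybrids
(8 of 60 sympatric bats are hybrids, so they dominate the error sets of the
better-performing cells). Cell-level values vary with the seed; the
published per-cell rates are not reproducible without the original
measurements — what the package reproduces exactly is the arithmetic that
sits on top of any such grid:

```r
glance(overlap_summary(reference_rates()))
#> # A tibble: 1 × 8
#>   overlap_mean overlap_sd contribution_mean contribution_sd ...
#> 1         25.9       5.76              18.3            9.25
```

i.e. a ~26% species overlap in sympatry of which hybrids contribute ~18%
overall (26.0 ± 1.13% via colour, 10.6 ± 4.24% via morphometry).

`fit_pca()`, `stepwise_wilks()`, `qda_crossval()`, `svm_ensemble()` and the
group statistics are all usable stand-alone and return tibbles or objects
with `tidy()`/`glance()`/`augment()`/`autoplot()` methods;
`run_full_analysis()` writes the complete report family plus a manifest to
a directory.

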