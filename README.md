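# nutricate

Heterogeneous treatment effects of maternal education on severe child
undernutrition under armed-conflict exposure.

`nutricate` is an end-to-end, tidyverse-style R pipeline for a
repeated cross-sectional survey design (two DHS-like rounds with
cluster GPS coordinates): it constructs the severe-undernutrition
outcome from anthropometry, builds spatial conflict and
environmental exposures, fits a from-scratch probit Bayesian Additive
Regression Trees (BART) model, and estimates counterfactual individual
and conditional average treatment effects (ITE/CATE) of maternal
education with bootstrap credible regions. Because the real microdata
(DHS, UCDP conflict events, flood/drought monitors) are
access-restricted, the package includes a synthetic-data generator
with exact ground truth, so the whole pipeline is testable offline.

## The model

The binary outcome — severe undernutrition — is the
severe-anthropometric-failure rule: a child is severely undernourished
when any of its WHO-style LMS z-scores (weight-for-age,
height-for-age, weight-for-height) falls more than 3 SD below the
reference median,

    z = ((x/M)^L − 1) / (L·S),    y = 1{ min(z_wa, z_ha, z_wh) < −3 }.

The outcome probability is a probit sum of m regularized trees with
the education level D among the predictors,

    P(Y = 1 | D = d, X = x) = Φ( Σ_{j=1..m} g(d, x; T_j, M_j) ),

fitted by MCMC with truncated-normal (Albert–Chib) latent
augmentation and grow/prune/change Metropolis–Hastings tree moves.
For each held-out test child, the covariate row is duplicated with
only the treatment column changed (observed level vs counterfactual
level); posterior probit draws are mapped through `pnorm()`, averaged
per arm, and differenced:

    θ_i = p̄_i(treated) − p̄_i(control),   CATE = mean_i θ_i,

so a negative value means education is protective. Credible regions
are 2.5/97.5 percentiles of the CATE over bootstrap refits of the
model on resampled training data. Conflict exposure is the mass of a
Gaussian kernel intensity surface over the 12 months preceding the
child's interview, in expected battle-related deaths per 0.1° grid
cell; a survey-constrained Voronoi partition (merged until every area
contains both rounds) provides a fine spatial control.

## Worked example

The packaged fixture is a small synthetic survey (300 children,
24 clusters, conflict events, environmental series) written by the
generator with a fixed seed.

```r
library(nutricate)

children <- read_children(system.file("extdata", "synthetic_children.csv",
                                      package = "nutricate"))
events   <- read_events(system.file("extdata", "synthetic_events.csv",
                                    package = "nutricate"))
ref      <- readr::read_csv(system.file("extdata", "synthetic_reference.csv",
                                        package = "nutricate"))
series   <- readr::read_csv(system.file("extdata", "synthetic_series.csv",
                                        package = "nutricate"))

cfg <- study_config(seed = 613, n_boot = 20,
                    bart = bart_config(num_trees = 50, burn_in = 200,
                                       num_draws = 200))
res <- run_analysis(children, events, ref, cfg, series = series)
res
#> Heterogeneous treatment effect analysis
#>   outcomes: 300 classifiable children, 0 unclassifiable excluded
#>   partition: 6 areas from 24 clusters
#>   exposures: mean conflict intensity 1.515
#>   split: 210 train / 90 test
#>   evaluate: AUC 0.551, cutoff 0.201
#> # A tibble: 6 × 6
#>   level analysis                delta_probability   lower     upper     n
#>   <int> <chr>                               <dbl>   <dbl>     <dbl> <int>
#> 1     1 untreated: level 1 -> 4          -0.0506  -0.124  -0.0112      19
#> 2     2 level 2 vs level 1               -0.00352 -0.0299  0.0101      11
#> 3     3 level 3 vs level 1               -0.0164  -0.0533  0.000414    19
#> 4     4 level 4 vs level 1               -0.0552  -0.112  -0.0127      14
#> 5     5 level 5 vs level 1               -0.0569  -0.102  -0.0182      14
#> 6     6 level 6 vs level 1               -0.0599  -0.125  -0.00986     13
```

`delta_probability` is the estimated change in the probability of
severe undernutrition when a child's mother holds the row's education
level instead of no education (level 1); for the untreated row the
contrast is observed level 1 against the 9-year compulsory-schooling
counterfactual. `lower`/`upper` are the bootstrap 95% credible region
(20 refits here, so the regions are coarse; the reference
configuration uses 1,000).

```r
res$roc
#> ROC: AUC = 0.551, cutoff = 0.201 (sensitivity 44.4%, specificity 73.6%)
summarize_ite(res$ite$theta)
#> ITE summary: n = 90, mean = -0.0407, sd = 0.0246
#>    2.5%     25%     50%     75%   97.5%
#> -0.0877 -0.0579 -0.0440 -0.0177 -0.0028

plot_cate_by_level(res$cate_by_level)   # effect sizes with regions
autoplot(res$roc)                       # ROC curve
write_results(res, "out/")              # cate_by_level.csv, ite.csv, ...
```

Lower-level entry points mirror the pipeline stages:
`compute_indicators()` (z-scores and the Bristol outcome),
`estimate_intensity()` / `assign_child_intensity()` (conflict
surfaces), `build_partition()` (survey-constrained Voronoi merge),
`fit_probit_bart()` / `predict_probit_draws()` (the sampler),
`build_counterfactual_design()`, `estimate_cate_from_draws()`,
`bootstrap_cate()`, `subgroup_cate()`, `roc_auc()`, and the generator
`generate_population()` / `true_cate()`.

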