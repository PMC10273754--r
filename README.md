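# asymnet — directed functional connectivity from delayed anti-symmetric correlations

`asymnet` is an R package for estimating *directed* whole-brain functional
connectivity from parcellated time series (typically resting-state fMRI) and
relating its graph-theoretical organisation to disease stage, pathology and
cognition. It is aimed at researchers studying functional integration and
segregation along the Alzheimer's disease continuum, but the machinery is
generic to any multivariate time series with lead–lag structure.

## The method in brief

Zero-lag correlation networks are symmetric and therefore undirected. This
package instead correlates every ordered region pair at a positive temporal
delay *d* (in repetition-time steps):

    C_d[i, j] = corr( x_i(1 .. T−d),  x_j(1+d .. T) )

so the row region leads. Any square matrix splits uniquely as
`C_d = S_d + K_d` with `S_d = (C_d + C_dᵀ)/2` symmetric and
`K_d = (C_d − C_dᵀ)/2` anti-symmetric; `K_d` is the directional component,
and `W = max(K_d, 0)` is a directed weighted network (`W[i,j] > 0` encodes
`i → j`). Per subject and delay the network is binarized across proportional
densities 5%–50% (step 1%), and binary directed clustering (Fagiolo) and
global efficiency are summarized by the area under their density curves
(AUC). Group differences in AUC are tested by label-permutation tests with
Benjamini–Hochberg FDR control; associations with amyloid/tau SUVRs and
cognitive scores use AIC-selected quadratic regressions with demographic
covariates and a 1.5-IQR outlier screen on the outcome.

Because suitable clinical data are access-restricted, the package includes a
synthetic-cohort generator: stable lagged vector autoregressions with
group-specific directed coupling templates, staged metadata (diagnosis,
amyloid/tau SUVRs, APOE ε4, cognitive scores), and a planted nonlinear
global-efficiency trajectory across the amyloid-positive groups
(decrease → increase → decrease). Every stage of the analysis is testable
against this known ground truth.

## Worked example

```r
library(asymnet)
library(dplyr)

# a reduced-scale cohort: 30 regions, 40 subjects in 4 staged groups
des <- default_cohort_design(seed = 42, n_regions = 30,
                             n_per_group = c(15, 10, 10, 5))
cohort <- simulate_cohort(des$groups, n_regions = 30, n_timepoints = 200,
                          seed = 42, jitter_sd = des$params$jitter_sd,
                          ar1 = des$params$ar1)

auc <- cohort_auc_table(cohort, delays = 1:2, step = 0.05)
auc |> filter(measure == "global_efficiency") |>
  group_by(group) |> summarise(mean_auc = mean(auc))
#>   group         mean_auc
#> 1 AD_Abeta_pos     0.242
#> 2 CN_Abeta_neg     0.261
#> 3 CN_Abeta_pos     0.257
#> 4 MCI_Abeta_pos    0.262
```

The group means reproduce the planted trajectory: efficiency drops from
amyloid-negative to amyloid-positive controls (0.261 → 0.257), rises in MCI
(0.262, the hyper-integration stage) and collapses in dementia (0.242).
Permutation tests with FDR correction flag exactly these contrasts:

```r
cmp <- compare_all_groups(auc, n_permutations = 500, seed = 42)
cmp |> filter(significant, measure == "global_efficiency") |>
  select(group_a, group_b, delay, observed_diff, p_fdr) |> head(4)
#>   group_a      group_b       delay observed_diff   p_fdr
#> 1 CN_Abeta_neg CN_Abeta_pos      1       0.00224 0.00871
#> 2 CN_Abeta_neg CN_Abeta_pos      2       0.00560 0.00479
#> 3 CN_Abeta_neg MCI_Abeta_pos     1      -0.00256 0.00479
#> 4 CN_Abeta_neg AD_Abeta_pos      1       0.0144  0.00479
```

`observed_diff` is the mean AUC difference (first minus second group); the
negative MCI contrast is the hyper-integration signature. Small building
blocks are available directly, e.g. an exact permutation test:

```r
permutation_test(c(10, 11, 12), c(0, 1, 2), n_permutations = 1000)
#> Permutation test (difference of means, exact enumeration)
#>   observed diff = 10, p = 0.1 (20 splits)
```

`run_analysis()` chains everything (AUC table → group contrasts →
association models) and writes CSV/JSON outputs; `tidy()`/`glance()` methods
cover the fitted objects and `autoplot()` methods the curves, comparison
tables, histograms and model fits. A thin command-line front end with
`simulate` / `connect` / `metrics` / `compare` / `associate` / `run`
subcommands lives at `inst/cli/asymnet.R`.

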