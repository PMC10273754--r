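---
title: "Delayed anti-symmetric connectivity: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed anti-symmetric connectivity: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymnet)
```

## The method

Functional connectivity estimated from zero-lag correlations is undirected:
the correlation matrix is symmetric by construction. This package implements
a delayed variant that recovers directionality. For a region-by-timepoint
matrix $X$ and a delay $d$ (in sampling steps, one step = one repetition
time, 3 s by default), the delayed correlation matrix is

$$C_d[i,j] = \mathrm{corr}\big(x_i(1\,..\,T-d),\; x_j(1+d\,..\,T)\big),$$

so the row region leads and the column region follows, using the $T-d$
overlapping samples (no padding or wraparound — truncation is the standard
estimator). Any square matrix splits uniquely into a symmetric and an
anti-symmetric part,

$$C_d = S_d + K_d,\qquad S_d = \tfrac{1}{2}(C_d + C_d^\top),\qquad
K_d = \tfrac{1}{2}(C_d - C_d^\top),$$

and $K_d$ carries exactly the directional excess: $K_d[i,j] > 0$ means
region $i$ leads region $j$ at delay $d$. The directed weighted network
keeps $W = \max(K_d, 0)$ elementwise, so at most one direction per pair
carries weight; negative entries are the mirror image of positive ones and
are set to zero. At $d = 0$, $K_0 \equiv 0$: the method is informative only
at delays $\geq 1$, and the pipeline refuses delay 0 rather than silently
computing a zero network.

Each subject's network, per delay, is binarized over a proportional density
sweep (default 5% to 50% of the $n(n-1)$ possible directed edges in steps of
1%, i.e. 46 graphs), keeping the $m = \mathrm{round}(D\,n(n-1))$ largest
weights. Because the support of $W$ is one direction per pair, densities
above 50% are unreachable; the achieved density is recorded with a warning.
On each binary directed graph two measures are computed:

* **clustering coefficient** (segregation): Fagiolo's binary directed
  generalization, $C_i = t_i / [d_i^{tot}(d_i^{tot}-1) - 2 d_i^\leftrightarrow]$
  with $t_i = \tfrac12[(A + A^\top)^3]_{ii}$, averaged over nodes. On
  pipeline inputs reciprocal edges cannot occur ($d_i^\leftrightarrow = 0$),
  but the implementation handles them for generality.
* **global efficiency** (integration): mean inverse directed shortest-path
  length over ordered pairs, with unreachable pairs contributing 0.

Each measure's curve across the sweep is summarized by its trapezoidal area
under the curve (AUC) against density expressed as a fraction, removing the
dependence on any single threshold. Group differences in AUC are assessed by
two-sample permutation tests on the difference of group means (10,000 label
permutations by default, add-one two-tailed p-values; exhaustive enumeration
is used automatically when the number of label splits is small enough),
corrected by Benjamini–Hochberg FDR at $q = 0.05$ across the whole family of
contrasts × measures × delays. Associations with pathology (amyloid and tau
SUVRs) and cognition are modelled per outcome and delay by ordinary least
squares on the amyloid-positive subjects, with age, sex, education and
cognitive status as covariates, the two measure AUCs and optionally their
squares as candidate terms, the dependent variable screened by the
1.5-interquartile-range rule, and the candidate set chosen by minimum AIC.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| delays | 1–5 | sampling steps | anti-symmetric part vanishes at 0; weight distributions narrow at long delays, so short delays carry the directed signal |
| density range | 0.05–0.50, step 0.01 | fraction of directed pairs | below 5% most nodes disconnect; above 50% unreachable on anti-symmetric support |
| permutations | 10,000 | count | p-value resolution ~1e-4 with add-one correction |
| FDR level `q` | 0.05 | — | conventional |
| IQR multiplier `iqr_k` | 1.5 | — | Tukey fences on the modelled outcome |
| amyloid cut-off | 1.11 (strict >) | SUVR | conventional positivity threshold; boundary value is negative |
| `tr_seconds` | 3 | s | sampling interval; one delay step = one TR |

Quartiles in the IQR screen use linear interpolation between order
statistics (R's default type 7). The AIC is $n\log(\mathrm{RSS}/n) + 2k$
with $k$ the number of mean parameters including the intercept; constant
offsets cancel in ranking at fixed $n$. Ties in AIC break toward fewer
terms, then enumeration order (candidate sets are enumerated smallest
first); a squared term is admitted only together with its linear term.
Anti-symmetry of the input to network construction is checked to
$\max|K + K^\top| \le 10^{-8}$; zero-variance overlap segments yield
correlation 0 with a warning rather than aborting a cohort run; a flat
region therefore cannot sink an analysis. Ties at the density cut break by
ascending (row, column) index for bit-reproducibility.

## What the synthetic cohort emulates

Real data for this kind of analysis (parcellated resting-state fMRI with
amyloid/tau PET staging) are access-restricted, so the package ships a
generator whose output has the statistical shape the analysis assumes. Each
subject's signal is drawn from a stable lagged vector autoregression
$x(t) = \sum_l B_l\,x(t-l) + \varepsilon(t)$, where the $B_l$ encode a
group-specific directed coupling template plus a common diagonal AR(1) term
(default 0.3) for within-region autocorrelation. Stability is enforced by
checking that the companion-matrix spectral radius is below 1 (templates are
rescaled onto a 0.9 margin; per-subject multiplicative strength jitter,
default 10%, is likewise guarded).

The default four-group design mirrors a staged amyloid-PET sample: 81
amyloid-negative controls, 36 amyloid-positive controls, 31 amyloid-positive
MCI and 18 amyloid-positive dementia subjects, 200 regions × 200 timepoints.
Group templates come from a hub-concentrated ring family with two levers:
`n_sources` (how few regions emit the strong couplings; concentrating
sources leaves many regions without strong afferents and depresses global
efficiency throughout the sweep) and `ring_prob` (regular ring propagation
versus random shortcuts). The defaults plant a decrease → increase →
decrease global-efficiency trajectory across the amyloid-positive groups.
Density and strength alone turned out not to move the AUC: proportional
thresholding is rank-based, and the stability cap on all-positive coupling
mass confines backbone influence to the lowest densities, so the topology
levers above were adopted instead. These parameters live in the design YAML
(`inst/extdata/design_default.yaml`), not in code.

Covariates are drawn from documented distributions loosely matched to such
cohorts (age ~ N(76, 7) years, education ~ N(16, 3) years, balanced sex,
group-dependent APOE ε4 copy numbers and cognitive/biomarker locations);
amyloid-negative SUVRs are Uniform(0.9, 1.11) and positive ones
Uniform(1.12, 1.6), so the strict 1.11 cut-off classifies every subject
consistently with its design group. Outcomes with a known quadratic
dependence on a network measure can be attached via `quadratic_link()`,
giving ground truth for the model-selection layer.

The generator deliberately omits hemodynamic response shapes, scanner
noise and drift, spatial geometry of regions, longitudinal change, and any
heterogeneity of within-group coupling topology beyond strength jitter
(within-group heterogeneity is a free parameter of the design, not an
inference about any real cohort). Passing tests therefore show that the
estimator chain is correct and well calibrated on data with known directed
structure — not that real fMRI satisfies the VAR assumptions.

One empirical subtlety: the narrowing of connectivity-weight distributions
with increasing delay (the reason the analysis stops at delay 5) emerges in
the generator only when the directed structure is concentrated at lag 1 and
its strengths are heterogeneous and dense enough to reach the weight
quartiles. With sparse homogeneous backbones the positive-weight IQR is
dominated by correlation sampling noise, which signal autocorrelation
suppresses precisely at delay 1, reversing the trend. The corresponding
property test generates its cohorts with a dense heterogeneous lag-1
backbone for this reason.

## Numerical and statistical choices

* The permutation statistic is the difference of group means — the standard
  choice for this design; it is documented rather than configurable-silent.
* Exhaustive enumeration replaces Monte-Carlo permutation automatically when
  $\binom{n_a+n_b}{n_a}$ does not exceed the permutation budget; exact
  p-values have no add-one correction.
* The IQR screen is applied to the model's dependent variable; which
  variable the screen targets is genuinely ambiguous in this family of
  analyses, so it is an explicit, documented argument.
* Minimum-AIC selection retains a known ~15% probability of admitting one
  spurious predictor per inactive candidate; exact recovery of the
  generating term set plateaus near 85–90% no matter how strong the signal.
  The reported selection-consistency rate should be read with that floor in
  mind.
* Variance inflation factors are reported as a collinearity diagnostic but
  never used to exclude terms.
* Group averages of directed networks may carry weight in both directions of
  a pair (subjects can disagree on orientation); they are returned as plain
  matrices flagged "average", not as directed networks.
* Histograms of connectivity weights exclude exact zeros: those are
  structural absences created by negativity-zeroing, not weights.

## Problem sizes used by the tests

The test and acceptance runs use reduced scales chosen to exercise every
code path with comfortable statistical power: cohorts of 30 regions × 200
timepoints with 40 subjects (15/10/10/5), delays 1–2, density step 0.05 and
500 permutations for end-to-end checks; 12-region networks for graph-measure
properties; exhaustive enumeration of all 4-node digraphs for the
measure-versus-oracle equivalence; 2,000 null replicates for permutation
calibration; and 50 Monte-Carlo seeds for parameter-recovery and
selection-consistency rates. The full-scale defaults (200 regions, 166
subjects, delays 1–5, step 0.01, 10,000 permutations) run the identical
code.

## Known limitations

* Lagged Pearson correlation captures linear, stationary lead–lag structure
  only; frequency-domain, windowed-dynamic and partial-correlation variants
  are out of scope.
* Per-pair sample alignment assumes complete series (enforced by the input
  invariant); pairwise-complete handling for real data with scrubbing or
  missing frames would need a documented extension.
* Edge-level inference (significance of individual connections) is not
  provided; inference operates on subject-level AUC summaries.
* The binary-directed clustering definition follows Fagiolo (2007); other
  toolboxes implement slightly different directed variants, and the oracle
  tests pin down exactly this implementation's semantics.
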