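---
title: "Methods: the Composite Coverage Index and its design-based inferential chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Composite Coverage Index and its design-based inferential chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccindex)
```

## The index

The Composite Coverage Index summarises eight preventive and curative
interventions along the maternal and child care continuum into one score per
woman–child record:

$$\mathrm{CCI} = \frac{1}{4}\left(\mathrm{FPS} +
\frac{\mathrm{SBA}+\mathrm{ANCS}}{2} +
\frac{2\,\mathrm{DTC3}+\mathrm{MSL}+\mathrm{BCG}}{4} +
\frac{\mathrm{ORT}+\mathrm{CPNM}}{2}\right)$$

Each of the four care domains — family planning, maternal/newborn care,
immunisation, case management of sick children — carries weight 1/4; within
the immunisation domain the three-dose pentavalent series counts double.
On the sixteenths scale the weights are FPS 4, SBA 2, ANCS 2, DTC3 2, MSL 1,
BCG 1, ORT 2, CPNM 2; they sum to one exactly (`cci_weights()` verifies this
to machine precision), and with all eight components observed, 16·CCI is an
integer. A record is classified **optimal** when CCI ≥ 0.50 and **partial**
otherwise. The boundary is deliberately inclusive: the package pins
`classify_cci(0.50) == "optimal"`.

### Not-applicable components

ORT is defined only for children with a recent diarrhoea episode, CPNM only
for children with a recent cough episode. Published descriptive tables
rarely state the denominator convention, so `compute_cci()` exposes four
policies and records which one was used:

* `renormalise` (default): drop the not-applicable components and rescale
  the remaining weights to sum to one. This makes the weakest assumption —
  it neither penalises nor credits an intervention the child had no occasion
  to receive — and keeps the score in [0, 1].
* `impute_zero` / `impute_one`: treat not-applicable as uncovered/covered.
* `drop_record`: score and label become `NA`.

When every component is applicable all policies coincide, which the test
suite asserts. Classification always happens per record on the raw score;
survey weights enter only at estimation time.

## Design-based estimation

All inference assumes a two-stage stratified cluster sample described by a
`svy_design()` (stratum, PSU/cluster, sampling weight). Variances use Taylor
linearisation with the with-replacement approximation: the variance of a
weighted total is estimated from the between-PSU variability of weighted PSU
totals within strata, with an $n_h/(n_h-1)$ factor. Finite-population
corrections and replicate-weight methods are out of scope.

Weights may be kept raw (inverse inclusion probabilities) or normalised to
mean one; every point estimate, standard error, test statistic and p-value
in the package is invariant to rescaling all weights by a constant, and the
tests assert this. A stratum with a single PSU is an error by default —
silent variance underestimation is worse than a failure — with an explicit
`single_psu = "centre"` option that centres the lonely PSU at the grand mean
of PSU totals.

Proportions (`svy_prop()`) are Hájek ratio estimates with logit-transformed
95% confidence intervals (kept inside [0, 1]) and a design effect relative
to simple random sampling of the same unweighted size, using the
$p(1-p)/(n-1)$ reference variance so that the design effect is exactly one
in the census/SRS limit.

### Rao–Scott corrected chi-square

`rao_scott_test()` computes the Pearson statistic on design-weighted cell
proportions scaled to the unweighted $n$, then applies the second-order
(Satterthwaite) correction: the generalised design-effect matrix is the
design-based covariance of the independence contrasts relative to their
multinomial covariance; the statistic is divided by
$\bar\delta(1+\mathrm{cv}^2)$ of its eigenvalues and the degrees of freedom
deflated by $1+\mathrm{cv}^2$. The multinomial reference covariance uses
$1/(n-1)$ so that under simple random sampling (equal weights, each element
its own PSU, one stratum) every generalised design effect equals one and the
corrected statistic reproduces the classical Pearson X² on the raw counts to
numerical precision — an identity the tests check at 1e-8. Two p-values are
reported: from the chi-square reference, and (printed by default, matching
common survey software) from an F reference whose denominator degrees of
freedom are the number of PSUs minus the number of strata. Under a clustered
null the F version holds its size: the acceptance suite estimates the type-I
error at α = 0.05 from 1,000 replicates and requires it inside
[0.035, 0.065].

### Design-based rank-sum test

`svy_ranksum()` replaces the outcome by pooled weighted mid-rank (ridit)
scores — ties averaged, scaled to the unit interval — and performs a
design-based Wald test that the mean rank score differs between the two
groups, reusing the same linearisation machinery. The exact rank-scoring
scheme is not fully pinned down in the applied literature; weighted
mid-ridits on the pooled sample are used because they reduce to the
classical mid-ranks under equal weights. Under equal-weight element sampling
the z statistic tracks the classical normal-approximation Wilcoxon z (tested
on average over simulation replicates), and the null p-values are uniform.

## Survey-weighted logistic regression

`svy_logit()` maximises the weighted Bernoulli log-likelihood by IRLS
(starting value β = 0, convergence when the coefficient change falls below
1e-10, cap of 25 iterations, fitted probabilities clamped at 1e-12 for
numerical stability; non-convergence raises a typed error carrying the last
β, and |β| > 15 raises a separation warning). The covariance is the
design-based sandwich with PSU-aggregated score totals. At equal weights the
estimates reproduce the classical MLE to 1e-6, which is tested against
`glm()` as an independent oracle.

**AIC under a pseudo-likelihood is not uniquely defined.** The package
normalises the weights to mean one inside the log-pseudolikelihood, so the
AIC scales with the sample size rather than the sum of weights and is
invariant to weight rescaling. `step_aic()` performs the backward search:
at each step the single term (categorical terms as whole blocks) whose
removal yields the lowest AIC is dropped; the search stops when no removal
lowers the AIC; exact ties (within 1e-9) are broken in favour of the term
earliest in the model formula, and every step is recorded in a trail. The
candidate set is per dataset — different survey rounds may legitimately
select different models.

`hosmer_lemeshow()` groups records by fitted probability into g = 10
weight-balanced groups (g is reduced with a warning when there are fewer
distinct fitted values, with a floor of 3) and refers
$\sum (O-E)^2/(E(1-\bar p))$ to a chi-square with g − 2 degrees of freedom.
Under a correctly specified model its rejection rate at α = 0.05 is required
to lie in [0.03, 0.08] over 500 replicates. Missing covariate values are
handled complete-case, with the dropped-row count stored on the fit.

## Spatial autocorrelation

The spatial unit is the administrative region. `build_weights()` turns a
symmetric adjacency list into binary or row-standardised weights
(row-standardised is the default for both the global and local statistics;
with only eight units, giving each region's neighbourhood equal total
influence is the conventional choice and makes the mean of the local
statistics equal the global one). `global_moran()` reports

$$I = \frac{n}{S_0}\,
\frac{\sum_{ij} w_{ij} (x_i-\bar x)(x_j - \bar x)}{\sum_i (x_i-\bar x)^2},
\qquad E[I] = -\tfrac{1}{n-1},$$

with a two-sided permutation p-value $(m+1)/(M+1)$ as the primary inference
— with $n = 8$ regions the normal approximation from the randomisation
moments is unreliable and is labelled approximate. `local_moran()` computes
$I_i = (z_i/m_2)\sum_j w_{ij} z_j$ with conditional permutations (unit i
held fixed, the remaining values shuffled) and classifies each unit into the
high-high / low-low / high-low / low-high quadrant purely from the signs of
the centred value and its spatial lag; the significance flag is separate and
never alters the quadrant. Constant surfaces raise an explicit
"zero variance" error rather than returning 0/0.

A power caveat that shaped the test design: with eight units, the
conditional-permutation significance of a local statistic has very little
power even for strong clustering, because a belt of three high-value regions
leaves each member with half its neighbours outside the belt. The simulation
test therefore validates the quadrant labelling of an engineered
high-partial-coverage belt against a paired run of the identical procedure
on a structureless configuration, rather than against the per-unit
significance flags. `regional_cci_surface()` defaults to the **partial**
coverage proportion per region (mapping low coverage is the convention for
targeting), with the class switchable.

## Classification tree

`grow_tree()` is a case-weighted Gini CART: recursive binary partitioning,
numeric/ordinal splits at midpoints between observed values, categorical
splits by the ordered-by-class-rate shortcut (exact for a binary response).
The applied literature on this analysis names both the Gini CART and the
conditional-inference tree; the two differ, and the Gini CART with case
weights is implemented because it is the fully specified variant — the
`min_improvement` stop (minimum Gini decrease as a fraction of root weight,
default 1e-3) plays the role a significance stop plays in
conditional-inference trees. Defaults: `max_depth = 5`,
`min_node_weight = 10` (in weight units, i.e. records when weights are 1).
No pruning by default. Survey structure enters only through the case
weights. Prediction is deterministic; missing split values route to the
heavier child, unseen categorical levels route to the heavier child with a
warning. The installed `rpart` implementation is used in the test suite as
an independent cross-check of the root split, never as the implementation.
Tree inputs in the pipeline are wired to the stepwise-selected variables,
not hard-coded.

## The synthetic-data generator

`generate_population()` builds a finite population that emulates the design
the analysis assumes: eight regions (Guinea's, with a hand-encoded adjacency
map), two strata per region (urban/rural), a configurable number of clusters
per stratum with log-normally varying sizes, covariates (wealth quintile,
maternal and partner education, media access, work status, marital status,
pregnancy planning, antenatal-visit category, child age/sex) drawn from
distributions resembling the published descriptive profile of a West
African DHS round, and the eight components drawn Bernoulli from logistic
models with known coefficients. Two features are deliberate:

* **wealth/region confounding** — a latent region + urban effect (strength
  is a config knob, default 1.0 for the urban shift) feeds the wealth
  quintile, so regional coverage differences partly reflect wealth, as the
  multivariate analysis must disentangle;
* **known truth** — the generating coefficients and the exhaustively
  evaluated population quantities (component coverages, per-region optimal
  and partial proportions, the marginal optimal share) are returned, so
  estimator calibration and parameter recovery are testable.

The component intercepts were calibrated once against the published 2012
descriptive coverages (family planning satisfied rare at ~9%, BCG
near-universal at ~89%, and so on); the coefficient pattern puts the wealth
gradient on every component and the strongest effects of four-plus
antenatal visits on the maternal-care components, the structure the
regression and tree stages are designed to detect. The default seed
(20180527) is recorded in the config output for reproducibility.

`draw_svy_sample()` implements the two stages: systematic PPS on a randomly
ordered cluster list (the standard field procedure; clusters whose PPS
probability reaches one are taken with certainty) and systematic random
selection of households within clusters. Weights are stored un-normalised as
inverse inclusion probabilities — the weight-scaling convention used in any
given published analysis is rarely stated, so both raw and mean-one
normalised weights are available at design level, and everything downstream
is invariant to the choice. Requesting all clusters and all households
yields a census with unit weights exactly.

What the generator does **not** emulate: household rosters beyond the
analysis fields, child mortality and the resulting exclusions, non-response,
multi-birth correlation within mothers, and any spatial structure beyond the
region effects. Passing tests on synthetic data therefore demonstrate that
the estimators are correct and calibrated under the declared design — not
that real-survey complications (informative non-response, recall error in
vaccination status) are handled.

## Problem sizes used by the checks

The test suite and acceptance script run at deliberately modest scales,
chosen as the smallest sizes at which the stochastic assertions are stable:
calibration simulations use 500–1,000 replicates on samples of a few hundred
records; parameter recovery uses 20 seeds at roughly 5,000 sampled records
(16 strata × 8 clusters × ~39 households) against a ~17,600-record
population; Monte-Carlo permutation checks use full enumeration where
n! is small. With 160 standardised recovery errors, a correctly calibrated
estimator exceeds 3 SE about 0.4 times in expectation, so recovery is
asserted through near-complete 3-SE containment plus empirical 95% CI
coverage in [90%, 99%], not through a zero-exceedance rule.

## Known limitations

* Taylor linearisation only; no jackknife/BRR/bootstrap replicate weights,
  no finite-population correction.
* Main-effects logistic models only (no interactions, no multilevel
  models, no multiple imputation) — matching the analysis the package
  reproduces.
* The eight-component index only; revised/extended index variants are out
  of scope.
* With eight spatial units, all spatial inference is permutation-based and
  low-powered; analytic p-values are descriptive.
* The published national estimates themselves require the restricted
  original microdata and are reproduced only structurally/directionally on
  synthetic data (wealth gradient, antenatal-care effect, spatial
  clustering), never numerically.
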