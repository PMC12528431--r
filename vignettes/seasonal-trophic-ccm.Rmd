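---
title: "Inferring seasonal trophic controls with convergent cross mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring seasonal trophic controls with convergent cross mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Multi-decadal plankton and trawl surveys sample a community a handful of
times per year. From such records one wants to know whether a focal prey
taxon — here, the archetype is a spring-blooming copepod whose fall
abundance sets the overwintering stock — is controlled from the bottom up
(strong spring cohorts feeding predator growth) or from the top down
(predators depressing the prey before winter), and which of several
candidate predators are actually involved. Correlations alone cannot
separate shared seasonal forcing from genuine dynamic coupling, which is
why this package combines three tools on season-specific interannual
series:

1. **Spearman rank correlations** between season pairings, with the sign
   conventions of trophic theory (bottom-up positive, top-down negative);
2. **boosted regression trees (BRTs)** to rank predators by predictive
   influence on the prey's spring and fall abundance; and
3. **convergent cross mapping (CCM)** with a seasonal-surrogate null to
   test directed dynamic coupling.

`seasonccm` implements the full pipeline — seasonal series construction,
the EDM/CCM kernel, the surrogate test, the BRT ranking, and an
orchestrator — plus seasonally forced predator-prey simulators with known
coupling structure, used throughout the test suite to validate the
pipeline end to end.

## Seasonal series construction

Survey records (`year, month, region, taxon, abundance_m3`) become annual
series in a fixed order: per-record ln(x+1) transform, then the yearly mean
over a season window, then gap filling, then z-normalization
(`prep_series()`).

* **Season windows** are spring = months 4–6, spring–summer = 4–9 (the
  predators' extended foraging window), fall = 10–12. No record outside the
  window ever contributes.
* **Transform before or after averaging?** Per-record ln(x+1) is the
  default (it stabilizes tow-level lognormal noise before pooling);
  `transform_mean = TRUE` transforms the yearly mean instead. The choice
  shifts values slightly but not ranks.
* **Gap filling.** Embedding methods need evenly spaced series, so missing
  years inside the observed range are filled by tricube-weighted local
  polynomial regression on the observed years only (`loess_fill()`). The
  span (default 0.5) is read as the fraction of observed points entering
  each local fit, with at least `degree + 2` points so the zero-weight
  boundary point never starves the fit; ties at the cutoff distance are all
  included. Degree 2 is the default, degree 1 available. Ends are never
  extrapolated: the series is truncated to the first-to-last observed year.
  Observed values are never altered, and the interpolated fraction is
  tracked (a warning fires above 30% — heavily interpolated series carry
  little interannual information).
* **Normalization** is `(x - mean) / sd` with the n−1 denominator, always
  the last step; with 30–45 annual points the n vs n−1 choice matters only
  in the third decimal, but it is fixed here for reproducibility. When two
  series are aligned on shared years inside the pipeline, normalization is
  re-applied to the aligned vectors so cross-mapped series always enter
  with mean 0 and variance 1.

## The EDM kernel

`delay_embed()` builds the Takens reconstruction
\((x_t, x_{t-\tau}, \dots, x_{t-(E-1)\tau})\); `simplex_forecast()` makes
leave-one-out nearest-neighbour forecasts with the simplex convention of
\(E+1\) neighbours weighted \(w_i = \exp(-d_i/d_1)\); `select_E()` picks
the embedding dimension maximizing one-step forecast skill (ties to the
smallest E, the more parsimonious reconstruction). `cross_map()` tests the
directed hypothesis X → Y by estimating X contemporaneously
(`tp = 0`) from Y's embedding; skill is the Pearson correlation between
estimates and observations, reported as a curve over library sizes
(default: 8 sizes from `E + 2` rows to all rows, 100 random subsets each)
and as the deterministic full-library skill. Rising skill with library
size — convergence — is the CCM signature of coupling; the package reports
`convergence_delta` and leaves the accept/reject decision to the surrogate
test, since no numeric convergence cutoff is well established.

Numerical details that matter: neighbour ties are broken by library order,
so results are bit-reproducible for a fixed seed; an exact-match neighbour
(distance 0) takes all the weight, the limit of the exponential kernel;
degenerate (constant) predictions raise an error rather than returning a
spurious correlation. The inner loop is C++ (as is conventional for EDM
packages); an exhaustive brute-force R implementation in the test suite
must agree to 1e-10 on every short-series configuration.

## The seasonal-surrogate significance test

The null model for "no coupling" must preserve the shared seasonal cycle —
the main confounder — while destroying everything else. A surrogate
(`seasonal_surrogate()`) keeps the mean cyclic trend over a fixed period
(default 12 steps; on annual series this is a 12-year cycle, the plausible
reading for interannual data) and permutes the residuals. Residuals are
permuted **within phase** by default, which conserves every phase mean,
the overall mean and the overall variance exactly — within a phase the
cycle is constant, so this is implemented as a bitwise permutation of the
raw values. A global permutation (`shuffle = "global"`) is available; it
preserves the residual multiset but lets residual mass move between
phases, so the conservation laws hold only in expectation.

`ccm_significance()` replaces the **driver** (the cross-mapped target) by
default — the hypothesis is that the effect's manifold encodes the driver,
so breaking the driver's temporal structure while keeping its seasonal
profile is the sharpest null; surrogating the effect is available. The
p-value is the add-one permutation estimator
\(p = (1 + \#\{\rho_{null} \ge \rho_{obs}\})/(1 + n_{surr})\) with 500
surrogates by default, so p is always positive and the test slightly
conservative. Significance is judged at the full library. Two asterisks
mark p ≤ 0.05, one marks p ≤ 0.10.

**Temporal exclusion radius.** Classic leave-one-out (excluding only the
target's own row) makes the surrogate test anti-conservative when the
driver is autocorrelated: embedding neighbours of an autocorrelated effect
series tend to be temporally adjacent, so the estimate of the driver at
time t borrows driver values at t ± 1, t ± 2 — information the surrogate
destroys. In a calibration study on independent AR(1) pairs
(\(\phi = 0.5\), n = 200, 100 replicates per setting) the rejection rate
at nominal 5% was 11% with no exclusion, 8% with radius 1, 5% with radius
2, 2% with radius 3; white-noise pairs were calibrated at every radius
(the within-phase permutation test is exact for phase-exchangeable
drivers). The significance layer therefore defaults to
`exclusion_radius = 2` — the smallest radius restoring the nominal size —
while the raw EDM primitives keep the classic convention
(`exclusion_radius = 0`). On 40–60-year annual series the exclusion
removes at most 4 of ~40 candidate neighbours per target, a negligible
power cost.

## BRT influence ranking

`fit_brt()` regresses the prey's spring (bottom-up proxy) or fall
(top-down proxy) series on the predators' spring–summer series with
gradient-boosted regression trees, following the slow-learning protocol
standard in ecology: learning-rate grid {0.001, 0.005, 0.01}, interaction
depth {1, 2, 3}, bag fraction 0.5, up to 5000 trees, 10-fold
cross-validation choosing the tree count that minimizes held-out squared
error, then a full-data refit at the winning setting. The tree ensemble is
fit by `xgboost`; both influence measures are computed by this package
from the dumped split structure:

* **selection frequency** — the percentage of split nodes that use each
  predictor (counting only splits that reduced training loss), the
  headline measure; and
* **split improvement** — each predictor's share of the summed
  squared-error reduction, the conventional gradient-boosting measure.

Both are normalized to 100%. They usually agree on the ranking; selection
frequency is flatter because it ignores how much each split helped.
`partial_dependence()` evaluates the marginal shape of each predictor's
effect by averaging predictions over the training rows with the predictor
pinned to grid values inside its observed range. The base score is the
response mean, so a null ensemble (no informative splits) predicts
`mean(y)` everywhere and its influence degrades gracefully to uniform.
BRTs use the normalized series, matching the CCM inputs.

## The synthetic community

The generators serve two roles: a unit-level benchmark and an end-to-end
testbed.

`simulate_coupled_logistic()` is the classic two-species coupled logistic
map; with \(\beta_{yx} = 0.32, \beta_{xy} = 0\) (X forces Y,
\(r_x = 3.8, r_y = 3.5\), n = 400 after a 100-step burn-in) the
true-direction cross map must beat the reverse — the package's
directionality benchmark. Because the map is exactly bilinear in
\((Y, Y^2, XY)\), least squares on the update rule recovers the planted
coefficients to machine precision, an oracle the tests exploit.

`simulate_seasonal_pp()` emulates the survey setting: monthly Ricker
dynamics with sinusoidal forcing of the prey growth rate
(\(r = 0.8, \alpha = 0.9, K = 1\)), predation pressure \(aP\)
(\(a = 1.2\)), predator conversion \(b a N\) (\(b = 0.5\)) and mortality
\(m = 0.3\)/month, a 10-year burn-in. Interannual variability enters as
**year-level lognormal carrying-capacity anomalies**
(\(\sigma_K = 0.3\)) — food-supply variation between years — plus small
monthly process noise (\(\sigma_{proc} = 0.1\)). This structure was chosen
because it is the simplest one reproducing the full qualitative mechanism
on the annual seasonal means: good food years raise the spring prey peak
(climatology peaks in months 3–6), fuel the predator through summer
(months 6–9), and end in below-average fall prey — so spring prey
correlates positively with spring–summer predator abundance and negatively
with fall prey. Monthly i.i.d. noise alone cannot do this: within-year
noise carry-over then dominates and the spring–fall correlation comes out
positive. With both noise SDs at zero the skeleton is a deterministic
periodic cycle (no interannual signal at all), which is why the noise
terms are integral to the generator rather than decoration.

`simulate_community()` surrounds the coupled pair with decoy predators
following independent seasonally forced Ricker dynamics (random phase and
growth rate, their own food anomalies) — sharing the seasonal cycle and
the interannual variance structure but none of the prey's signal, exactly
the confound the surrogate test must not mistake for coupling.
`observe_survey()` adds the observation model: six bimonthly cruises per
year, multiplicative lognormal tow noise (SD 0.2 on the log scale), and
whole survey years dropped with probability 0.1, matching the gappiness
of real survey archives; both knobs are configurable.

What the generator does **not** emulate: stage structure and diapause
timing, advective exchange between regions, spatially stratified sampling,
and observation error that varies with gear or season. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers known
coupling under realistic sampling noise, seasonal confounding and missing
years — not that it is robust to every feature of real survey data.

## A known limitation: same-year carry-over direction

On the synthetic community the pipeline cleanly separates the coupled
predator from decoys (the planted-recovery test demands the coupled
predator be the only 95%-significant top-down cell *and* the top BRT
influence in at least 80% of 30 replicates, and the false-positive rate
stay at or below nominal when coupling is zeroed). One contrast observed
in real survey analyses that it does **not** reproduce is the asymmetry of the prey's same-year
spring → fall self-coupling test: in the generator both seasonal
series are functions of the same latent year state (the food anomaly plus
the within-year cascade), and contemporaneous CCM on ~60 annual points
cannot order them — the forward and reversed self-pairings fire at similar
rates. The reversal mode (`fall_to_spring`) is implemented and reported,
but its insignificance should not be treated as a property the synthetic
testbed can guarantee.

## Problem sizes and reproducibility

Defaults are chosen for ~40–60-year annual series: E is scanned over
1..min(10, n/3); 100 library subsets per size; 500 surrogates. The test
suite and the acceptance script use the study conditions (60-year
communities, 30 replicates for planted recovery, 100 seeds for
directionality, 200 null replicates at n = 200 for calibration) with
reduced BRT grids ({0.005, 0.01} × depth 1–3, 1500 trees) where a full
grid search would add nothing but runtime. Every stochastic step is
seeded: simulators draw per-taxon substreams from the community seed,
the pipeline derives one substream per report cell (so any single cell
re-run in isolation reproduces the full-run result bitwise), and each
surrogate runs in its own substream of the test's master seed.

## A worked example

```{r, eval = FALSE}
library(seasonccm)

com <- simulate_community(n_years = 60, n_predators = 5, coupled = 1, seed = 1)
rec <- community_survey(com, region = "A")

report <- run_full_study(rec, regions = "A", prey = "prey",
                         predators = com$predators,
                         brt_cfg = brt_config(learning_rate = c(0.005, 0.01),
                                              max_trees = 1500),
                         seed = 1)
print(report)
write_report(report, "report")
```

The report table lists, per region and predator, the bottom-up and
top-down Spearman correlations with p-values, the full-library cross-map
skill, the surrogate-test p-value and its asterisks, alongside the prey's
spring-to-fall carry-over row; the influence table carries both BRT
measures per response season; `ccm_curves.json` holds the library-size
convergence curves and null quantiles for plotting.
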