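# seasonccm

Season-specific trophic-control inference from multi-decadal survey time
series.

Ecological surveys sample plankton and fish a few times a year for decades.
From such records, `seasonccm` asks whether a focal prey taxon — the
archetype is a spring-blooming copepod whose fall abundance sets the
overwintering stock — is controlled from the bottom up (strong spring
cohorts fuelling predator growth) or the top down (predators depressing
the prey before winter), and which of several candidate predators are
involved. It is aimed at quantitative ecologists working with interannual
abundance series.

## What it computes

Three complementary analyses on season-window annual series
(ln[abundance + 1], gap-filled by local regression, z-normalized):

* **Spearman rank correlations** between season pairings — spring prey ↔
  spring–summer predator (bottom-up, expected positive) and spring–summer
  predator ↔ fall prey (top-down, expected negative) — with two-sided
  t-approximation p-values.
* **Convergent cross mapping (CCM).** For the directed hypothesis X → Y,
  the effect series Y is delay-embedded (Takens reconstruction; embedding
  dimension E chosen by simplex projection) and states of the driver X are
  estimated from each point's E+1 nearest neighbours, weighted
  w_i = exp(−d_i/d_1). Coupling is indicated when the cross-map skill
  ρ = cor(X̂, X) rises with library size. Significance comes from a
  seasonal-surrogate null: surrogates preserve the mean cycle over a fixed
  period and permute the residuals within phase;
  p = (1 + #{ρ_null ≥ ρ_obs}) / (1 + 500). Two asterisks mark p ≤ 0.05,
  one marks p ≤ 0.10.
* **Boosted regression trees (BRTs)** ranking predators by relative
  predictive influence (%) on spring and fall prey abundance —
  selection frequency (share of split nodes) and split improvement (share
  of error reduction), both normalized to 100% — with cross-validated
  learning rate, tree depth and tree count, plus partial dependence
  curves.

A seasonally forced predator–prey simulator with known coupling structure
(monthly Ricker dynamics, year-level food-supply anomalies, a survey
observation model with tow noise and missing years) backs the test suite:
the pipeline must recover a single planted predator among decoys end to
end.

## Worked example

```r
library(seasonccm)

com <- simulate_community(n_years = 60, n_predators = 5, coupled = 1, seed = 11)
rec <- community_survey(com, region = "A")   # survey records, 6 cruises/year

td <- run_direction_test(rec, directed_hypothesis("top_down", "prey", "pred1"),
                         region = "A", seed = 1)
print(td)
#> top_down [A]: pred1(spring_summer) -> prey(fall), n = 60 years
#>   Spearman rho = -0.859 (p = 1.51e-18); E = 3; CCM skill = 0.773, p = 0.001996 **
```

Reading the output: the planted predator's spring–summer abundance is
strongly negatively correlated with fall prey abundance (top-down sign),
the fall prey series was embedded at E = 3, the full-library cross-map
skill is 0.77, and it exceeds all 500 seasonal-surrogate nulls
(p = 2/501 ≈ 0.002, "**") — directed dynamic coupling, not just shared
seasonality. The same test on an uncoupled decoy (`pred3`) prints skill
0.024 and p = 0.40 (no asterisk).
`run_full_study()` assembles all cells (carry-over, bottom-up, top-down,
both BRTs) into a report table; `write_report()` serializes it to CSV and
JSON.

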