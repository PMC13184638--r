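---
title: "Phase-aware drought exposure and two-stage county count models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-aware drought exposure and two-stage county count models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtphase)
```

## The problem

Drought is a slow-moving hazard whose psychological burden plausibly
depends not only on how severe conditions are, but on where a community
sits in the drought's lifecycle: anticipatory stress while conditions
worsen versus recovery-related stress while they improve. `droughtphase`
implements an ecological time-series design for studying that question
with rare count outcomes (firearm and nonfirearm suicide) observed as
county-month panels: drought-index percentiles are turned into phase-aware
exposure categories, each county gets its own negative-binomial count
model, and county effects are pooled into national incidence rate ratios
(IRR) and absolute risk differences (ARD).

Restricted mortality files cannot be redistributed, so the package ships a
seeded synthetic panel generator with the same statistical structure. All
claims made by the test suite are claims about that generator plus the
published summary tables; see the final section for what that does and
does not establish about real data.

## Exposure construction

Monthly dryness percentiles (100 = driest month on record relative to the
local climatology for that calendar month) are binned into U.S. Drought
Monitor style categories. The default edges follow the USDM percentile
convention — D4 at or above the 98th dryness percentile, D3 95–98, D2
90–95, D1 80–90, D0 70–80, wet categories mirrored, NEUTRAL between — and
are configurable, since percentile conventions differ slightly across
monitoring products. Intervals are closed on the left; the monotonicity of
the map (drier percentile never yields a wetter category) is tested as an
invariant.

A *drought event* is a maximal run of D1–D4 months lasting at least two
consecutive months (`min_duration`, configurable); shorter excursions are
treated as anomalies without plausible mental-health consequences, and D0
does not sustain an event. Within an event, *cumulative drought intensity*
(CDI) is the running sum of monthly severity scores (D1 = 1 … D4 = 4), so
it grows with both severity and duration and resets when the event ends.

The event is split where cumulative CDI reaches 50% of the event total:
months whose running CDI is at most half the total form the *worsening*
phase, the rest the *improving* phase. Two numerical choices needed
fixing:

* **Inclusive boundary.** A month that lands exactly on 50% belongs to the
  worsening phase. This keeps palindromic severity profiles (e.g.
  1-2-3-3-2-1) splitting exactly at their midpoint.
* **Severe onset fallback.** If the first month alone exceeds half the
  total CDI (e.g. severities 4-1-1), the first month is still labeled
  worsening, so both phases are non-empty for every qualifying event.

Each event month is then labeled by crossing its phase with its
*contemporaneous* severity bucket — moderate-to-severe (D1–D2, `M2SD`) or
severe-to-exceptional (D3–D4, `S2ED`) — giving four drought labels; wet
months outside events are `WET`, and everything else (NEUTRAL, D0,
sub-threshold runs) is `NONE`. The six labels partition every series, an
invariant the suite checks against an independent brute-force enumerator
on all severity sequences up to length six.

```{r exposure-example}
cats <- c("NEUTRAL", "D1", "D2", "D3", "D3", "D2", "D1", "W2")
data.frame(category = cats, label = label_months(cats))
```

## Stage 1: county negative-binomial models

For each county (and outcome, and optionally stratum) the package fits

\[
\log E[Y_t] = \log \mathrm{pop}_t + \beta_0 + \gamma_{x(t)}
  + \text{season}_t + f(\mathrm{temp}_t) + g(t)
\]

with a negative-binomial likelihood whose dispersion is estimated by
maximum likelihood. `exp(γ)` is the IRR of exposure category `x` against
the `NONE` reference. Season enters as a four-level meteorological factor
(DJF/MAM/JJA/SON) — the minimal faithful reading of "adjusted for season"
alongside a separate long-term time smooth. The smooths `f` and `g` are
*unpenalized* natural cubic splines whose basis dimension is `k − 1` for a
k-knot configuration. Fitting fixed-dimension bases inside a conventional
NB GLM (rather than penalized smoothers) makes the AIC parameter count
literal — columns plus one for the dispersion — which keeps model
comparison across the knot grid exactly reproducible without committing to
any penalization scheme, and it is roughly an order of magnitude faster,
which matters for the replicated recovery studies in the test suite.

Knot complexity is chosen per county by AIC over the grid k_temp ∈
{2,3,4,5} × k_time ∈ {3,4,5,6} (16 fits per county). Ties break toward
parsimony: smallest `k_temp + k_time`, then smallest `k_temp`. The modal
pair across counties is reported as a diagnostic only; the county-best
fits feed the meta-analysis (a config switch fits one fixed pair, e.g.
4-4, everywhere instead). Degenerate inputs are handled explicitly: a
constant temperature or time column collapses its spline term (dropped and
flagged); exposure levels never observed in a county produce no estimate
for that county-category pair; all-zero counts take the non-convergence
path; a dispersion drifting to the Poisson boundary is capped at 10^5 and
the fit retained with the capped likelihood.

## Stage 2: random-effects pooling

County log-IRRs are pooled per category with inverse-variance
random-effects meta-analysis (REML between-county variance by default,
DerSimonian–Laird as a switch), Wald 95% intervals on the log scale. Two
inclusion rules are available: the default stability rule keeps estimates
with standard error at most 2 on the log-IRR scale (boundary inclusive —
"greater than 2" excludes strictly above), and a minimum-population rule
(10,000/25,000/30,000) supports sensitivity comparisons. Pooled plots and
tables carry a coverage flag: `over85` when strictly more than 85% of the
eligible counties (all counties present in the input panel) contributed.

ARDs convert relative into absolute effects: ARD = α (IRR − 1)/IRR, where
α is the baseline rate over `NONE` person-time in the stratum, expressed
per million persons per month. The transform is monotone in IRR, so 95%
bounds are the same transform of the interval endpoints, which is exact
for monotone maps of an interval.

## The synthetic generator

The generator emulates, with one seeded draw per county stream:

* **Drought**: a stationary Gaussian AR(1) (default persistence 0.95,
  matching a 12-month smoothed index) mapped through its exact marginal
  distribution to dryness percentiles, so long-run category occupancy
  equals bin width while runs persist for months. `emulate_table1_mix()`
  rescales the bin edges so the long-run label mix approximates the
  national 2000–2018 climatology (≈56% none, ≈28% moderate-to-severe,
  ≈10% severe-to-exceptional, ≈6.5% wet).
* **Population**: log-normal across counties, median 25,000 and
  `sdlog = 1.5`, matching the spread of US county populations, with the
  heavy lower tail producing the small, unstable counties the inclusion
  rules act on. Annual population is constant within the panel.
* **Counts**: negative-binomial with mean
  `pop × baseline × exp(season + f(temp) + trend + γ_exposure)`. The
  default baseline, 7.16 deaths per million per month, is the national
  firearm baseline implied by the published IRR/ARD pair
  (α = ARD·IRR/(IRR−1) = 0.704·1.109/0.109). Default dispersion is
  `size = 20`: at rare-count means the law is nearly Poisson, with
  overdispersion emerging at metro-scale means — a modest inflation over
  Poisson, which is how real mortality counts behave. (A small `size`
  would impose a constant coefficient of variation at every population
  scale, which no mortality series shows.)
* **Covariates**: sinusoidal temperature with county-specific amplitude,
  mild spring-peaking seasonality, and a slow upward secular trend
  (+0.13%/month) on the log rate.
* **Planted effects** default to the headline national estimates of this
  literature (firearm: 1.031/1.109/1.094/1.024 across the four drought
  phases), so recovery tests target realistic effect sizes.

Strata are produced by multinomial thinning of total counts with fixed
fractions, which preserves totals exactly and approximately preserves the
marginal count structure per stratum.

What the generator does **not** emulate: spatial correlation of drought
across counties (each county draws independently), population trends and
migration, the geography of urbanicity, and reporting artifacts in cause
assignment. Passing tests therefore demonstrate the pipeline's internal
correctness and its behaviour under the assumed data-generating structure,
not the validity of the published substantive estimates.

## Problem sizes used by the checks

The replicated recovery study uses 50 replicates of 200 counties × 228
months with the fixed 4-4 knot combination (the config-switch variant;
the 16-fit grid is exercised separately per county and in the acceptance
script's single full-scale run), and 30 planted-null replicates of 100
counties. Oracle comparisons run on deliberately tiny instances (≤ 20
observations, 5-study meta-analyses) where grid-search likelihood
maximization is exact enough to be an independent referee.

## Known limitations

* **Selection bias of the SE-filtered two-stage design at realistic
  sparsity.** In small counties a drought-phase category spans only ~10–25
  months; expected deaths there are often below 1. Counties with zero
  deaths in a category get enormous standard errors and are removed by
  the SE ≤ 2 rule, so among sparse counties only those that happened to
  observe deaths survive — a zero-truncation selection that biases
  county log-IRRs upward. Estimated standard errors also shrink with the
  observed count, so randomly high estimates receive larger
  inverse-variance weights. At the generator's US-like defaults (200
  counties), the pooled severe-to-exceptional worsening estimate
  overshoots a planted log(1.109) by roughly +0.08 log units and the
  replicated 95% CI coverage of the planted value falls well short of
  nominal; the corresponding recovery test records this honestly rather
  than passing. Scaling county populations (or pooling thousands of
  counties so that metro estimates dominate the weights, as the real
  analysis does) shrinks but does not in general eliminate the effect.
  One-stage hierarchical models or continuity-corrected pooling would
  avoid it, but fall outside this design.
* The worsening/improving split is a deterministic function of the
  realized severity path; measurement error in the drought index
  propagates directly into phase assignment near the 50% boundary.
* Eligibility denominators for the 85% coverage label default to all
  counties in the input panel; other conventions (e.g. all counties with
  at least one death) change the flag, not the estimates.
* The percentile bin edges are a convention, not an estimate; analyses at
  a different timescale (6 vs 12 months) should re-derive percentiles
  from the corresponding index, which the labeling engine treats as a
  pass-through.
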