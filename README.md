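# droughtphase

Phase-aware drought exposure classification and two-stage negative-binomial
modeling of rare county-month health outcomes, with random-effects pooling
into incidence rate ratios (IRR) and absolute risk differences (ARD).

## The problem

Drought is a slow-onset hazard: the stress a community experiences
plausibly differs while conditions are still worsening versus once they
have begun to improve. Studying that with suicide mortality requires
(1) turning a monthly drought-index series into exposure categories that
carry both *severity* and *lifecycle phase*, and (2) estimating rare-count
associations across thousands of heterogeneous counties. `droughtphase`
implements that full pipeline for epidemiologists working with
county-month panels (drought-index percentiles, mean temperature,
population offsets, death counts), plus a seeded synthetic-panel generator
so everything is testable without restricted mortality files.

## Method at a glance

**Exposure.** Dryness percentiles are binned into U.S. Drought Monitor
style categories (D0–D4, W0–W4, NEUTRAL). A *drought event* is a run of
D1–D4 lasting ≥ 2 consecutive months. Within an event, cumulative drought
intensity (CDI) is the running sum of severity scores (D1 = 1 … D4 = 4);
the event splits where CDI reaches 50% of its total — months at or below
half are the *worsening* phase, the rest *improving*. Crossing phase with
contemporaneous severity (D1–D2 vs D3–D4) gives four drought labels,
`M2SD_WRS`, `S2ED_WRS`, `S2ED_IMP`, `M2SD_IMP`, alongside `WET` and
`NONE`; the six labels partition every series.

**Stage 1.** Per county and outcome, a negative-binomial count model

    log E[Y_t] = log pop_t + β0 + γ_exposure + season + f(temp_t) + g(t)

with unpenalized natural-spline smooths whose complexity is chosen per
county by AIC over the knot grid k_temp ∈ {2,…,5} × k_time ∈ {3,…,6}
(16 fits). `exp(γ)` is the IRR against the no-drought reference.

**Stage 2.** County log-IRRs with standard error ≤ 2 are pooled per
category by random-effects meta-analysis (REML, DerSimonian–Laird
optional); results carry a flag for whether more than 85% of counties
contributed. ARD = α (IRR − 1)/IRR converts each pooled IRR into
additional cases per million persons per month, where α is the baseline
rate over `NONE` person-time.

## Worked example

```r
library(droughtphase)

# a synthetic national panel: 25 counties x 19 years, drought persistence
# and exposure mix tuned to the 2000-2018 US climatology
cfg <- emulate_table1_mix(sim_config(n_counties = 25, n_months = 228,
                                     seed = 42))
res <- run_pipeline(cfg, outcomes = "deaths_firearm", knots = c(4, 4))

res$summary$county_months
#>   category    n   pct
#> 1     NONE 3196 56.07
#> 2 M2SD_WRS  779 13.67
#> 3 S2ED_WRS  298  5.23
#> 4 S2ED_IMP  352  6.18
#> 5 M2SD_IMP  835 14.65
#> 6      WET  240  4.21

res$effects[res$effects$category == "S2ED_WRS",
            c("category", "irr", "ci_low", "ci_high", "alpha", "ard",
              "n_included", "coverage_flag")]
#>   category      irr   ci_low  ci_high  alpha      ard n_included coverage_flag
#> 2 S2ED_WRS 1.271281 0.955476 1.691466 7.2778 1.553022         14       under85
```

Reading the output: 56.1% of simulated county-months had no drought;
the pooled severe-to-exceptional worsening IRR of 1.27 (95% CI 0.96–1.69)
says firearm-suicide rates in those months were elevated about 27%
relative to no-drought months in this small sample (the generator plants
1.109 — see the vignette on the upward selection pressure of the SE
filter at this sparsity); with a baseline rate α of 7.3 deaths per
million per month that corresponds to 1.6 additional deaths per million
persons per month. Only 14 of 25 counties yielded a stable estimate for
this category — the `under85` flag warns that the pooled value does not
represent most counties, exactly the caveat this design needs at small
scale.

A shell wrapper with the same pipeline is in
`inst/scripts/run_pipeline.R` (`simulate`/`csv` modes, knot grid, SE or
population threshold, output directory).

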