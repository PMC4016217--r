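# habvalue

Tools for valuing the breeding habitats of itinerant colonial breeders —
species, like the Tricolored Blackbird, whose colonies move among nesting
substrates (cattail marshes, Himalayan blackberry, stinging nettles,
thistles, triticale grain fields, willows) from year to year. Because no
site is used every year, per-nest reproductive success alone misranks
habitats: what matters for conservation is the **time-averaged
reproductive output** of a typical site. `habvalue` computes it from the
data colony-monitoring programmes already collect.

## What it computes

From site × year presence–absence surveys, colony sizes and per-colony
reproductive success, the package estimates, per nesting substrate *s*:

* **occupancy** (occupied / surveyed site-years) and annual **turnover** —
  cessation-of-use events over *possible* cessations (site occupied in
  year *t−1* and surveyed in year *t*) and colonizations over possible
  colonizations — with exact binomial (Clopper–Pearson) intervals, plus
  the corresponding logit-link binomial mixed models (substrate + year
  effects, year random intercept) and ANOVA-style variance partitions
  with partial eta-squared h² = SS_e / (SS_e + SS_err);
* **colony longevity** — maximal runs of consecutive occupied years,
  censored by the study window and unsurveyed years, fit with a censored
  Weibull accelerated-failure-time model, log T = μ_s + σW, by explicit
  maximum likelihood (σ < 1 means the abandonment hazard declines with
  colony age);
* **reproductive success** — RS (chicks per nest, failures included), RSS
  (chicks per successful nest) and the nest failure rate, linked by the
  exact identity RS = RSS × p(success), with the 2/3 birds→nests and
  1.5 nests→birds conversions, and a linear mixed model with colony
  random intercepts;
* the headline index —

  **x = RS × (2/3 × mean birds)**, its propagated SD
  **x·√(s₁² + s₂²)** (s₁, s₂ the coefficients of variation of size and
  RS), and the occupancy-adjusted output **x × occupancy**, in chicks
  per site per year.

A synthetic metapopulation generator (two-state Markov occupancy,
lognormal colony sizes, zero-inflated nest outcomes, incomplete
monitoring) supports end-to-end validation by parameter recovery.

## Worked example

Simulate a survey under the default study-scale conditions, run the whole
pipeline, and rank substrates:

```r
library(habvalue)
cfg <- default_sim_config(seed = 1)
sim <- simulate_metapopulation(cfg)

series <- build_occupancy_series(sim$survey)
tr     <- score_transitions(series, colonization_start_year = 2006)
tv     <- substrate_turnover_rates(tr, series, min_records = 5)

sp  <- extract_spells(series)
sp4 <- sp[sp$substrate %in% c("blackberry", "cattail-marsh",
                              "thistle", "grain-field"), ]
fit_weibull_aft(sp4, reference = "cattail-marsh")
#> Censored weibull AFT model: 120 spells (47 events, 73 censored)
#>             term estimate    se      z        p
#> 1    (Intercept)   1.0298 0.106  9.705 2.87e-22
#> 2  subblackberry  -0.0337 0.295 -0.114 9.09e-01
#> 3 subgrain-field  -0.6176 0.128 -4.838 1.31e-06
#> 4     subthistle   0.0921 0.248  0.371 7.11e-01
#> scale (sigma) = 0.3899; log-likelihood = -75.907

rs <- substrate_rs_summary(sim$reproduction, min_records = 5)
sz <- decadal_summary(sim$reproduction, recent_window = c(2005, 2011))
hv <- habitat_value_table(rs, sz$recent, tv)
print(hv[, c("substrate", "rs_mean", "chicks_per_colony",
             "occupancy", "chicks_per_site_year")], digits = 3)
#>       substrate rs_mean chicks_per_colony occupancy chicks_per_site_year
#> 1        nettle   1.651             232.7     0.727                169.2
#> 2    blackberry   1.729             465.6     0.194                 90.1
#> 3       mustard   0.471             277.2     0.216                 59.9
#> 4   grain-field   0.470             310.4     0.192                 59.5
#> 5 cattail-marsh   0.644              95.4     0.351                 33.5
#> 6       thistle   0.631             118.6     0.240                 28.5
#> 7        willow   0.609              47.3     0.576                 27.2
#> 8       bulrush   0.599              45.0     0.273                 12.3
```

Reading the output: the AFT location for cattail marsh (1.03 on the
log-year scale) and the strongly negative grain-field shift (−0.62) say
grain-field colonies are abandoned much sooner — these fields are
harvested — while σ ≈ 0.39 < 1 says sites that survive their first year
are safer afterwards. In the index table, stinging nettle ranks first
despite middling colony sizes because its sites are occupied in 73% of
years; grain fields host the biggest colonies (≈1000 birds) but frequent
failure and low occupancy push them mid-table. This is the qualitative
pattern that motivates managing for dependable substrates, not just
large colonies.

Field data in any of the three supported CSV dialects enter the same
pipeline through `read_survey_table(path, schema)` with
`schema ∈ {"portal", "hamilton", "statewide"}`.

## Documentation

The methods vignette (`vignettes/habitat-value-methods.Rmd`) describes
the models, their assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
and known limitations.
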