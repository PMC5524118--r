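# heartsentinel

National-scale surveillance of acute cardiovascular events — and estimation
of how many events a prevention initiative averted — requires combining three
administrative sources that each see part of the picture: a survey-weighted
emergency-department (ED) sample, a near-census hospitalization file, and the
death registry. `heartsentinel` implements that methodology as a tested R
pipeline:

1. **Event ledger** — classify records against editable ICD-style code lists
   (primary diagnosis for ED/hospitalization, underlying cause for deaths),
   apply the disposition exclusion cascade that makes the three sources
   mutually exclusive (ED: died/transferred/admitted removed;
   hospitalization: elective/died/transferred removed; deaths kept), and
   tabulate weighted counts with SDs.
2. **Rates** — stratum rates per 100 000 by sex × age group (18–44, 45–64,
   65–74, ≥75) and direct age-standardized rates with normal CIs.
3. **Trend model** — for each stratum, an inverse-variance-weighted
   log-linear fit of rate on calendar year,
   `ln r_y = a + b (y − y₀)`, `w_y = (r_y / se_y)²`, giving the annual
   percent change `APC = 100 (e^b − 1)`, its SE and CI by the delta method,
   and the modeled anchor-year (2011) rate `e^a` with SE from the centered
   design.
4. **Counterfactual baselines** — *stable* (anchor rate held constant) and
   *trend* (anchor rate compounded by the APC) expected rates for 2012–2016,
   with uncertainty propagated by Monte Carlo simulation (1000 draws of the
   anchor rate and APC per stratum).
5. **Events prevented** — `prevented = expected − observed` with pooled
   variance, `z = prevented / √(sd²_obs + sd²_exp)`, significant at
   `|z| ≥ 1.96`; positive values are events prevented, negative are excess
   events.

A synthetic multi-source generator (`sim_config()` / `simulate_events()`)
with known log-linear ground truth stands in for the restricted national
files, so the full pipeline is testable — including the type-I error of the
prevented-events test and recovery of injected rate deficits.

## Worked example

```r
library(heartsentinel)

cfg <- sim_config(seed = 20)        # national-condition defaults, 1/100 scale
run <- run_pipeline(cfg, n_sims = 1000)
print(run)
```

```
Cardiovascular event surveillance run
  seed 20; fit window 2006-2011 (anchor 2011); projection 2012-2013; 1000 sims
  overall age-standardized rate: 1136.3 (2006) -> 1024.9 (2011), change -9.8%

Trend fits:
Trend fits for 8 strata (anchor year 2011)
   sex age_group               apc       p modeled_rate
   men     18-44 -3.5 (-5.9, -1.0) 0.00621        122.5
   men     45-64 -1.6 (-3.0, -0.2) 0.02368       1016.6
   men     65-74 -2.9 (-4.6, -1.1) 0.00141       2453.0
   men       75+ -2.5 (-3.7, -1.2) 0.00020       6051.1
 women     18-44  -1.6 (-5.4, 2.3) 0.42257         91.9
 women     45-64  -1.4 (-3.2, 0.4) 0.11685        656.8
 women     65-74  -0.8 (-2.8, 1.2) 0.42247       2009.3
 women       75+ -2.1 (-3.2, -1.0) 0.00022       6006.3

Overall events prevented (expected - observed):
Events prevented (positive) / excess events (negative)
 strategy   scope     years observed expected          prevented      z
   stable overall      2012    23872    24099    227 (-545, 999)   0.58
   stable overall      2013    23093    24099   1006 (285, 1727) 2.74 *
   stable overall 2012,2013    46965    48198    1234 (14, 2454) 1.98 *
    trend overall      2012    23872    23613  -258 (-1037, 520)  -0.65
    trend overall      2013    23093    23143     51 (-708, 809)   0.13
    trend overall 2012,2013    46965    46757 -208 (-1473, 1058)  -0.32
```

Reading the output: the synthetic world declines ~9.8% over 2006–2011, each
stratum gets an APC with CI and p-value against slope = 0, and observed
2012–2013 totals are compared with both counterfactuals. Here the stable
baseline (rates frozen at 2011) credits 1234 prevented events (z = 1.98,
significant), while against the continuing-trend baseline the difference is
indistinguishable from zero — the same qualitative contrast the two-baseline
design is meant to expose. Intermediate tables are in `run$rates`,
`run$std_rates`, `as.data.frame(run$fits)`, `run$projections`,
`run$prevented`; `write_outputs(run, dir)` exports everything as CSV with a
config-hash header.

Published summary estimates can be projected directly, without microdata:

```r
fit <- apc_summary_fit(anchor_rate = 152.9, apc = -2.1, anchor = 2011)
round(project_baseline(fit, "trend", 2012:2016), 1)
#>   2012   2013   2014   2015   2016
#>  149.7  146.5  143.4  140.3  137.3
```

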