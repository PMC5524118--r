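---
title: "Multi-source cardiovascular event surveillance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source cardiovascular event surveillance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartsentinel)
```

## The surveillance problem

No single U.S. data system tracks both fatal and nonfatal acute
cardiovascular events. National monitoring therefore combines three
administrative sources: a survey-weighted emergency-department (ED) sample, a
near-census hospitalization file, and the vital-statistics death registry.
Because one clinical episode can surface in more than one source (an ED visit
that becomes an admission; a hospitalization that ends in death), events are
made *mutually exclusive* by a disposition-based exclusion cascade before the
three sources are summed.

`heartsentinel` implements that pipeline end to end — case classification,
exclusions, weighted tabulation with uncertainty, stratified and
age-standardized rates, weighted log-linear trend models, counterfactual
baseline projection with Monte Carlo uncertainty, and observed-vs-expected
inference — together with a synthetic multi-source generator so every stage
can be validated against known ground truth.

## Case definition and exclusion cascade

Events are classified by prefix match of the dot-stripped diagnosis code
against editable YAML code lists (`read_case_definitions()`): primary
diagnoses (ICD-9-CM style) for ED and hospitalization records, underlying
cause of death (ICD-10 style) for registry records. The two code systems
never cross, and a pattern may not belong to two event categories; violations
raise errors rather than silently resolving. The shipped default lists are a
plausible demonstration configuration, not an authoritative registry
definition.

The cascade then drops

* ED visits where the patient died in the ED, was transferred to another
  hospital, or was admitted to the same hospital, and
* hospitalizations that were elective, ended in in-hospital death, or were
  transferred out,

while death-registry records are never dropped. Exclusions can only shrink
counts, and each retained record contributes to exactly one source total;
both properties are tested.

## Counts, variances, and rates

Counts are weighted sums of records per year × sex × age group × source
(ED records carry survey weights; other records weight 1), kept as reals
internally and rounded only for display. Each count's SD comes from a
configurable per-source model (`sd_model()`):

* **design** (default): `sd = sqrt(sum(w_i^2) + (rel_se * count)^2)`. The
  `sum(w_i^2)` term is the classical variance estimator for a weighted total
  under Poisson-type record sampling; it reduces to the Poisson count
  variance for unit weights and captures the ED survey-weight design effect.
  The relative-SE term represents design overdispersion (defaults: 3% ED,
  0% hospitalization, 0.5% death registry).
* **relative**: `sd = rel_se * count`, mimicking published survey SDs
  directly.

The design model is the default because it matches the noise actually present
in the synthetic data, which keeps all downstream inference calibrated: if
the declared variances understated the generative noise, the prevented-events
z-test below could not hold its nominal size. Source totals are summed per
stratum with variances added (sources are disjoint and independent).

Rates are `1e5 * count / population` with SE scaling the same way. Direct age
standardization uses fixed standard-population weights over the four adult
age groups (18–44, 45–64, 65–74, ≥75; the default approximates the 2010 U.S.
Census adult distribution: 0.481/0.347/0.093/0.079). The standardized-rate
variance is `sum(weight^2 * se^2)` — age groups treated as independent, since
the cross-group covariance of the underlying estimates is not available — and
CIs are the symmetric normal approximation `rate ± 1.96·SE` throughout the
package. No gamma/exact intervals are used, matching the symmetric intervals
conventional in this surveillance setting.

## The trend model

For each of the eight sex × age strata, `apc_fit()` fits

\[
\ln r_y = a + b\,(y - y_0), \qquad w_y = 1/\widehat{\mathrm{Var}}(\ln r_y)
       = (r_y/\mathrm{SE}_y)^2,
\]

by weighted least squares over the fit window (default 2006–2011), with the
design centered on the anchor year \(y_0\) (default 2011, the last fit-window
year) so that the intercept is the modeled log anchor rate and its SE is read
directly off the coefficient covariance. The annual percent change is
\(\mathrm{APC} = 100(e^b - 1)\), with delta-method SE
\(100\,e^b\,\mathrm{se}(b)\) and CI \(100(e^{b \pm 1.96\,\mathrm{se}(b)}-1)\).

Two deliberate numerical choices:

* **Known-variance (meta-analytic) standard errors.** The coefficient
  covariance is \((X'WX)^{-1}\) with \(W\) built from the declared rate
  variances, not the residual-scaled OLS estimate. With only six annual
  observations, residual-scaled SEs combined with normal quantiles would
  undercover badly (about 88% for a nominal 95% interval); known-variance SEs
  are calibrated whenever the declared variances are honest, which the
  variance model above guarantees. All tests use the standard normal
  reference (z, not t), consistent with the 1.96 threshold convention.
* **Zero or negative rates abort the fit** with a clear error rather than a
  continuity correction; national-scale strata never approach zero, and a
  silent correction would distort the weights.

`compare_apc()` tests equality of two strata's slopes with
\(z = (b_a - b_b)/\sqrt{se_a^2 + se_b^2}\). Parameter recovery, CI coverage
(within [0.92, 0.98] empirically), and the type-I error of the comparison are
all exercised in the test suite against the generator's known APCs.

## Counterfactual baselines

From each stratum fit, two expected-rate paths are projected past the anchor
year (`project_baseline()`):

* **stable** — the modeled anchor rate held constant;
* **trend** — the anchor rate compounded year-on-year by the fitted APC:
  \(r_{y} = r_{y_0}\,(1+\mathrm{APC}/100)^{\,y-y_0}\).

Uncertainty is propagated by simulation (`simulate_baseline()`, default 1000
replicates): each replicate draws the anchor rate from
\(N(\hat r_{y_0}, \mathrm{se})\) truncated at zero and, for the trend
strategy, a single APC from \(N(\widehat{\mathrm{APC}}, \mathrm{se})\), then
projects deterministically. Three choices deserve note:

* The draw distribution is normal on the natural scale (with a `lognormal`
  switch) because the published intervals this mirrors are symmetric.
* One APC draw per replicate is compounded across all years — the projection
  error in successive years is perfectly correlated within a replicate, as it
  should be when a single fitted trend is extrapolated.
* Anchor-rate and APC draws are independent; the covariance they share
  through the common fit is ignored because centering the design at the
  anchor year makes the coefficient estimates orthogonal only approximately
  (exactly, when the weights are equal). The residual covariance is small and
  documented rather than modeled.

Expected events are `rate × population / 1e5` with normal CIs from the
simulated rate SD.

## Events prevented

With `prevented = expected − observed` (positive = prevented, negative =
excess), the test statistic is

\[
z = \frac{\mathrm{expected} - \mathrm{observed}}
        {\sqrt{\mathrm{sd}_{\mathrm{obs}}^2 + \mathrm{sd}_{\mathrm{exp}}^2}},
\]

flagged significant at \(|z| \ge 1.96\). The observed total's variance is
included because the ED component of the observed count is itself a survey
estimate; `observed_fixed = TRUE` reproduces the variance-free-observed
variant.

Aggregation is done two ways, deliberately:

* **Across strata** — differences and variances sum
  (`combine_prevented()`); strata have disjoint data and independent fits, so
  independence is exact.
* **Across years within a stratum** — the two projection years derive from
  the *same* simulated draws and are therefore strongly correlated (perfectly
  so under the stable strategy). `run_pipeline()` sums expected events
  across years *inside* each draw and takes the SD across draws, which
  captures this covariance exactly. Summing per-year variances instead would
  understate the combined variance by nearly a factor of two and inflate the
  combined z; the package does not do that, even though the per-year
  `combine_prevented()` shortcut remains available for truly independent
  pieces.

## The synthetic generator

`sim_config()`/`simulate_events()` emulate the statistical structure of the
three sources: stratum-level true rates following exact log-linear trends,
events allocated to sources, disposition flags drawn independently per
record, lognormal ED survey weights, and Poisson count noise around a
gamma-distributed rate multiplier whose relative SD mirrors the per-source
overdispersion defaults. A single master seed spawns per-stratum substreams,
so adding strata never reshuffles existing draws and identical seeds give
byte-identical output.

Defaults encode national adult surveillance conditions: 2011 anchor rates
from 106.3 to 7031.0 per 100 000 across the eight strata and APCs from −1.1
to −3.4 %/yr, back-projected to 2006 as pre-exclusion base rates; a source
mix (14.7/73.2/12.1% ED/hospitalization/death before exclusions) chosen so
the post-exclusion shares land near the observed 12/74/14%; and populations
at 1/100 of the 2010 Census adult distribution so a default eight-year run
produces a few hundred thousand records in about a second rather than tens of
millions. Because base rates are pre-exclusion, observed synthetic rates sit
roughly 11% below the anchor inputs (the default cascade retains ~89% of
weighted events); ground truth for tests comes from `true_parameters()`,
which reports both scales.

What the generator does **not** emulate: hospital-cluster survey designs and
their Taylor-linearized variances, the 2012 inpatient-sample redesign,
state-coverage variation, person-level linkage across sources, or coding-era
transitions. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under honest sampling noise — not that
real survey files can be ingested unchanged.

## Calibration experiments and problem sizes

Two end-to-end experiments in the test suite define what "calibrated" means
here:

* **Null size.** In a world with all true APCs = 0, the overall 2012–2013
  prevented-events z-test rejects in ≈5% of 500 replicates.
* **Deficit recovery.** When post-2011 rates are suppressed 3% below the
  stable baseline, the estimated prevented total covers the injected deficit
  in well over 90% of replicates.

These experiments run at stratum populations of 60 000 with a light ED weight
model (mean 2, log-SD 0.3), a scale chosen so that every dominant source
count is large enough (hundreds to thousands per cell) for the normal
approximations the method relies on — the regime the method actually targets,
where national counts are 10^5–10^6. At much smaller populations the ED
sample degenerates to a record or two per cell and the z statistic acquires
small-sample bias that says nothing about the method itself. Module tests use
smaller configurations (populations of 20 000, short year ranges) where only
closed-form identities, not asymptotic calibration, are asserted.

## Known limitations

* Published survey SDs can be reproduced only through the configurable
  variance models; the package does not re-implement complex-survey variance
  estimation.
* Standardized-rate and multi-year CIs assume independence across age groups
  and (for the shortcut combiner) across combined units.
* The trend model is a single log-linear segment; joinpoint or segmented
  trends and autocorrelation-robust errors are out of scope.
* Events are episodes, not persons: no deduplication across transfer chains
  is attempted beyond the exclusion cascade.
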