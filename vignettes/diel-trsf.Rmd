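---
title: "Temporal resource selection along the diel cycle: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal resource selection along the diel cycle: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieltrsf)
```

## The idea: time as habitat

Resource selection functions compare where an animal was observed with what
was *available* to it. `dieltrsf` applies the same logic to the 24-hour
light–dark cycle: the "habitat units" are five astronomical time categories
— day, dawn, dusk, night, and deep night — whose availability (hours on
offer) varies with date and latitude. A raccoon photographed mostly at
night in a short-night midsummer week is telling us more about selection
than the same counts would in midwinter; the availability offset makes that
distinction formal.

The package covers the full path from raw camera-trap photo records to
selection estimates:

1. **Diel schedules** (`diel_schedule()`, `schedule_for_instant()`,
   `diel_category()`): sun-geometry boundaries and availability hours.
2. **Event processing** (`dedupe_events()`, `assign_categories()`,
   `compute_trap_nights()`): photo bursts to independent detection events.
3. **Covariates** (`ndvi()`, `buffer_proportion()`, `center_and_scale()`):
   site-level urbanization predictors, scaled for the model.
4. **Model** (`trsf()` and methods): hierarchical Bayesian multinomial
   selection model with availability offsets.
5. **Inference** (`predict()`, `nocturnality()`, `odds_ratio()`,
   `city_activity()`, `site_activity()`): the reported quantities.
6. **Synthetic data** (`sim_truth()`, `simulate_sites()`,
   `simulate_detections()`, `recovery_experiment()`): ground-truth data for
   end-to-end validation.

## Diel categories from sun geometry

For a calendar date and location the package computes, on the absolute
(UTC) timeline:

* **dawn** — from the start of morning astronomical twilight (sun centre at
  −18°) until the bottom edge of the sun touches the horizon (centre at
  −0.3°, the conventional refraction-plus-semidiameter altitude);
* **day** — from the end of dawn to the start of dusk;
* **dusk** — from the evening −0.3° crossing to the end of evening
  astronomical twilight (−18°, when it is dark enough for astronomical
  observation);
* **deep night** — one hour either side of the solar nadir (the sun's
  lowest point), 2.0 h by construction;
* **night** — the remaining dark intervals on both sides of the deep-night
  window.

Design choices that matter:

* **Solar algorithm.** Solar position uses the NOAA solar-calculator
  equations (Meeus-class series for declination and the equation of time;
  events from the hour-angle identity with two fixed-point refinements).
  Stated accuracy is well under a minute for 1900–2100 at the latitudes
  supported; the test suite checks dawn/sunrise/sunset/nadir instants
  against an independent low-precision Astronomical Almanac implementation
  with numerical root finding, at a ±2 min tolerance. Ephemeris-grade
  libraries built on the same event altitudes (−18° and −0.3°) agree to a
  similar tolerance.
* **Cycle frame.** Schedules run from one solar noon to the next, so the
  nadir ± 1 h window is always contiguous and night intervals spanning
  civil midnight are never split across schedules. Whether availability
  should be computed from the civil day or the enclosing solar cycle is
  genuinely open; the solar cycle is the only choice that keeps deep night
  whole, and it is what `schedule_for_instant()` implements.
* **Boundaries** are half-open `[start, end)`: an instant exactly on a
  boundary belongs to the later category.
* **Timezones.** All arithmetic is UTC; local timestamps are converted
  through the IANA database, so daylight-saving transitions change nothing
  but the parsing of local times. A schedule's cycle length differs from
  24 h only by solar-noon drift (seconds).
* **High latitudes.** Where the sun never reaches −18° (or never crosses
  the horizon) the five-category scheme is undefined. The package raises a
  classed error (`dieltrsf_no_twilight`) naming the missing event rather
  than substituting a different twilight definition: a silent fallback
  would change the meaning of the availability offset. Continental-US
  study latitudes never trigger this.
* **Near-degenerate geometry.** Around latitude 48° at midsummer the
  evening −18° crossing can fall inside the deep-night window. Deep night
  takes precedence: dusk (and symmetrically dawn) is clipped at the window
  edge and the night interval collapses to zero, so the five categories
  always partition the cycle and availability hours stay non-negative.

## From photos to detection events

A camera triggers many times while one animal lingers. Within each
(station, species) stream, `dedupe_events()` groups photos with the
**chain rule**: a photo starts a new event iff its gap to the previous
photo exceeds the window (15 min by default). "All photos within a 15-min
period" can also be read as a window anchored at the first photo of the
event; that variant is available as `rule = "anchor"` for sensitivity
checks. The event timestamp is the first photo's — it is the instant that
gets categorized. Deduplication is idempotent, order-invariant, and never
increases the event count; these are tested properties.

`assign_categories()` attaches the event's diel category, the five
availability hours of its enclosing solar cycle, and the city's mean
temperature on the event's civil date (the date of the timestamp in the
site's timezone; for small-hours events one could argue for the preceding
evening's date, but the timestamp's own date is the simpler, documented
choice). Events without a temperature record are flagged, and only dropped
on request. Trap nights count `floor()` of each deployment interval's
length in nights — the convention is logged because field protocols differ.

## Covariates

Site predictors summarize the urban environment inside a fixed-radius
buffer matched to each species' home-range scale (500 m, 1 km, or 1.5 km
are typical): available greenspace (proportion of land-cover cells in a
configurable class set), impervious cover, vegetation cover (proportion of
NDVI cells above 0.2), and human population density. The package operates
on user-supplied projected grids (`raster_grid()` is a deliberately
minimal matrix-plus-geometry container; `buffer_proportion()` uses
cell-centre-in-circle membership and excludes no-data cells from the
denominator) or directly on a prepared covariate table — acquiring and
reprojecting national land-cover or census products is data plumbing that
stays outside the package.

`center_and_scale()` prepares covariates the way multi-city hierarchical
designs require: **city-mean centring** (coefficients measure within-city
gradients, unconfounded by among-city differences and insensitive to
unequal city sample sizes) and division by the **global** standard
deviation (a one-unit change is one SD of the pooled data). Daily mean
temperature is scaled the same way over all detection events of the
species (over site-days in the generator); whether the global SD should be
taken over events or site-days is not settled, and the choice is recorded
with the scaling metadata, which also enables exact back-transformation.

## The selection model

With `day` (k = 1) as the reference, event `i` in city `c[i]` with scaled
covariates `x_i` and availability hours `alpha_{i,k}`:

$$y_i \sim \mathrm{Categorical}(\phi_i), \qquad
\phi_{i,k} = \frac{e^{\lambda_{i,k}}}{\sum_{k'} e^{\lambda_{i,k'}}}$$

$$\lambda_{i,k} = \begin{cases}
\log \alpha_{i,1} & k = 1\\
x_i^\top \beta_{\cdot,k} + b_{c[i],k} + \log \alpha_{i,k} & k > 1
\end{cases}$$

Reference-category coefficients are pinned at zero, which resolves the
softmax's shift invariance. With all coefficients and intercepts at zero
the model collapses to $\phi_k = \alpha_k / \sum_k \alpha_k$ — exactly the
availability-weighted distribution of a resource selection function with
an exponential link. `exp(beta) > 1` therefore reads as *selection* for a
category relative to day per unit (1 SD) covariate increase; `< 1` as
avoidance.

**Priors.** Selection coefficients get Laplace (double-exponential)
shrinkage priors with a common estimated rate: a fully Bayesian LASSO that
pulls weakly supported coefficients toward zero. Two parameterization
conventions are easy to trip over and are fixed here explicitly:

* the Laplace parameter `pi` is a **rate**, density
  $(\pi/2)e^{-\pi|x|}$ (the JAGS `ddexp` convention), with a
  Uniform(0.001, 10) prior;
* city intercepts are $b_{c,k} \sim \mathrm{Normal}(\mu_k, \tau_k)$ with
  `tau_k` a **precision**, `tau_k ~ Gamma(1, 1)`, and
  `mu_k ~ Normal(0, variance 10)`.

**Sampling.** `trsf()` runs an adaptive random-walk
Metropolis-within-Gibbs sampler written in C++: scalar Metropolis updates
for each coefficient and city intercept against cached linear predictors
(so an update costs one pass over the affected events, not a full
likelihood evaluation), conjugate Gibbs draws for `mu_k` and `tau_k`, and
an exact inverse-CDF draw from the truncated-Gamma full conditional of
`pi`. Step sizes adapt toward 0.44 acceptance during burn-in only, so the
post-burn-in chain is a fixed Markov kernel. One master seed derives all
per-chain seeds deterministically; identical seeds give identical draws.
Caches are rebuilt from the current state every 512 iterations to stop
floating-point drift.

The default protocol is the full-scale one — 14 chains, 20,000 burn-in,
thinning by 7, 75,000 kept draws (split across chains, rounded up) — and
desk-scale work passes a smaller `trsf_control()`. Convergence is judged
by the classic Gelman–Rubin statistic (`gelman_rubin()`), with the
criterion R-hat < 1.1 per parameter; the split-half variant is reported
alongside because classic R-hat cannot see a trend shared by all chains.
Zero within-chain variance everywhere makes the statistic undefined and is
reported as `NA` with a warning. Fits that miss the criterion return
normally with `converged = FALSE` and a warning — results are never
silently discarded. Categories with zero observed events are estimated
anyway (prior-dominated) and named in a warning.

## Reported quantities

All posterior summaries are medians with central (equal-tailed) 95%
credible intervals, computed per draw so that every probability vector
sums to one exactly.

* `predict()` evaluates activity probabilities at a covariate setting, at
  the population level (intercept means `mu_k`), for a named city, or for
  a hypothetical new city (`level = "new_city"` draws an intercept from
  its hyperdistribution — the interval then widens as `tau_k` falls).
* `nocturnality()` is the night + deep-night probability.
* `odds_ratio()` compares nocturnality odds after a +1 or +2 SD shift in
  one covariate against the reference (city-mean) setting. Conditioning
  follows a documented, configurable convention: other covariates at 0,
  availability fixed at the study-wide mean vector, population-level
  intercept unless a city is named. Draws where a probability is
  numerically 0 or 1 are excluded and counted. Whether such predictions
  should instead average over cities or standardize availability to equal
  hours is not settled; both conditionings are available through the
  `level` and `alpha` arguments.
* `city_activity()` gives per-city profiles plus the among-city average;
  `site_activity()` ranks sites from least to most nocturnal and reports
  the range.

## The synthetic-data generator

Field data cannot ship with the package, so `sim_truth()` defines a
ground-truth study and the generator draws data **from the model itself**:
city centres at continental-US latitudes (30–45°N, matching the span of
the study cities), 10 cities of 24–113 sites (lognormal around the design
mean of ~45), seasonal sinusoidal temperatures with daily noise, site
covariates with between- and within-city spread (proportions on a logistic
scale, density on a log scale), city intercepts drawn from their
hyperdistribution, event counts per site-day as a Poisson stand-in for
abundance (the selection model has none), categories drawn from the exact
model probabilities, timestamps uniform within the category's intervals
(night: over the union, proportional to interval lengths), and photo
bursts whose gaps sit far inside the 15-min window. Default effect sizes
are of the magnitude reported for common urban mammals (nocturnal
selection around ±0.2 log odds per SD). Events that would start within 15
min of the previous burst at the same station are dropped at generation,
which is what makes the round trip exact: deduplication plus
categorization reproduces the generator's ledger event for event.

What the generator does *not* emulate — imperfect detection, lure effects,
camera failure, spatial autocorrelation within cities, non-Poisson
clustering of visits, scaling mismatch between the temperature a category
draw used and the civil-date temperature a pipeline run would join — bounds
what passing tests show about field data: they validate the *computations*,
not the field sampling process.

`recovery_experiment()` closes the loop: simulate, fit, and score coverage
of the true coefficients, bias, RMSE and convergence, replicate by
replicate, with failures recorded rather than hidden.

## Validation scale and numerical choices

The automated checks run at desk scale, sized so the whole suite stays in
the minutes range: availability invariants over 1,000 random date/location
draws (|lat| ≤ 50°); likelihood equality with a brute-force oracle to
1e-10 on ≤10-event instances; softmax row sums to 1e-12; the null
offset property both analytically and on a ~10,000-event null fit
(expecting ≥90% of exponentiated coefficients' intervals to cover 1); and
50 replicates of simulate-2,000-events → fit with 4 chains / 2,000 burn-in
/ 5,000 kept — the full protocol scaled down — expecting 95%-interval
coverage of the true coefficients in [0.90, 0.98] and R-hat < 1.1
throughout. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

Other numerical conventions: softmax rows are stabilized by row-max
subtraction; a zero probability on an observed category returns a flagged
`-Inf` log-likelihood; `pi` draws are clamped to the prior support after
the inverse-CDF step; proposals that would make a softmax denominator
non-finite are rejected outright.

## Known limitations

* Polar and near-polar latitudes are out of scope by design (hard error).
* Lunar covariates, civil/nautical twilight schemes, occupancy-style
  detection correction and spatial autocorrelation are not modelled.
* The sampler is tuned for data on the scale of thousands to tens of
  thousands of events with a handful of covariates; very large designs
  would warrant a gradient-based backend targeting the same posterior.
* Species identity is taken at face value (exact string match); synonym
  mapping is the caller's responsibility.
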