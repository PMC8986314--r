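# dieltrsf

Temporal resource selection along the 24-hour diel cycle, from camera-trap
data.

Wildlife in cities cannot always move away from people in space, but they
can move away in *time*. `dieltrsf` treats the diel cycle as habitat: each
detection event falls in one of five astronomical time categories — day,
dawn, dusk, night, deep night — whose availability (hours on offer) shifts
with date and latitude, and a hierarchical Bayesian multinomial model
estimates selection for each category along urbanization gradients
(available greenspace, impervious cover, vegetation cover, human
population density, daily mean temperature). It is written for ecologists
analysing multi-city camera-trap networks, and for anyone who needs
availability-corrected diel activity estimates.

## The model

With `day` (k = 1) as the reference category, detection event *i* in city
*c*[*i*] with scaled covariates *x_i* and availability hours α<sub>i,k</sub>:

> y_i ~ Categorical(φ_i),  φ\_{i,k} = exp(λ\_{i,k}) / Σ\_k' exp(λ\_{i,k'})
>
> λ\_{i,1} = log α\_{i,1};  λ\_{i,k} = x_iᵀ β\_{·,k} + b\_{c[i],k} + log α\_{i,k}  (k > 1)

The log-availability offset makes the null model reduce exactly to
φ_k = α_k / Σα — the availability-weighted distribution of a resource
selection function with an exponential link — so exp(β) > 1 reads as
selection for a time category (relative to day) per 1-SD covariate
increase, and exp(β) < 1 as avoidance. Priors: β ~ Laplace(0, rate π)
(Bayesian LASSO shrinkage, π ~ Uniform(0.001, 10) estimated from the
data), city intercepts b ~ Normal(μ_k, precision τ_k) with
μ_k ~ Normal(0, 10) and τ_k ~ Gamma(1, 1). Fitting is by an adaptive
Metropolis-within-Gibbs MCMC sampler written in C++ (default protocol:
14 chains, 20,000 burn-in, thin 7, 75,000 kept draws), with classic
Gelman–Rubin R-hat (< 1.1) as the convergence criterion. See
`vignettes/diel-trsf.Rmd` for assumptions, parameterization conventions
and design decisions.

## Worked example

The synthetic-data generator draws a full multi-city dataset from the
model with known coefficients, so the whole pipeline can be exercised —
and checked — without field data:

```r
library(dieltrsf)

truth <- sim_truth(n_cities = 4, sites_per_city = 8,
                   start = "2017-04-01", end = "2017-05-10",
                   beta = matrix(c(0.4, 0, 0.3, 0.2,      # greenspace
                                   -0.3, 0, -0.4, 0),     # pop_density
                                 2, 4, byrow = TRUE,
                                 dimnames = list(c("greenspace", "pop_density"),
                                                 NULL)),
                   events_per_site_day = 1, seed = 42)
net <- simulate_sites(truth)
det <- simulate_detections(truth, net)

# photos -> deduplicated events -> categories + availability + temperature
events <- assign_categories(dedupe_events(det$photos), net$sites,
                            net$temperature)

fit <- trsf(category ~ greenspace + pop_density, data = det$ledger,
            city = "city_id",
            control = trsf_control(n_chains = 4, burn_in = 2000, thin = 1,
                                   kept_total = 5000),
            seed = 1)
fit
```

```
Temporal resource-selection model (hierarchical multinomial)
Events: 1289 across 4 cities; reference category: day
Detections by category:

       day       dawn       dusk      night deep_night
       548         38        127        463        113
Chains: 4, kept draws: 5000; max R-hat = 1.009 (converged, < 1.1)
```

`summary(fit)` prints posterior medians, 95% credible intervals and
exponentiated medians for every selection coefficient. Here the true
positive greenspace→night effect (0.3) is recovered with an interval
excluding zero, while null coefficients are shrunk toward zero by the
Laplace prior:

```
                    parameter median  lower upper  rhat exp_median excludes_zero
        beta[greenspace,dawn]  0.158 -0.074 0.539 1.002      1.171         FALSE
       beta[greenspace,night]  0.279  0.122 0.431 1.002      1.322          TRUE
      beta[pop_density,night] -0.159 -0.412 0.053 1.002      0.853         FALSE
                          ...
```

Reported quantities follow directly from the posterior:

```r
odds_ratio(fit, covariates = "pop_density")   # nocturnality odds, +1/+2 SD
```

```
    covariate shift    median     lower    upper excludes_one n_dropped
1 pop_density     1 0.8871332 0.7009443 1.089347        FALSE         0
2 pop_density     2 0.7919850 0.4915880 1.219531        FALSE         0
```

A median of 0.89 says this synthetic species is about 11% *less* likely to
use nighttime hours one SD of human density above the city mean (the
generating effect was negative); the interval still overlaps 1 at this
sample size. `predict(fit)` gives the population-level activity profile
(probabilities summing to 1 across the five categories):

```
    category     median       lower      upper
1        day 0.43329741 0.280384254 0.57074349
2       dawn 0.02700206 0.009408307 0.07153974
3       dusk 0.08292187 0.030915252 0.20427108
4      night 0.35326099 0.170502147 0.57555075
5 deep_night 0.08324715 0.032308936 0.18223651
```

`city_activity(fit)` and `site_activity(fit, covariates)` give the
per-city and per-site breakdowns; `plot(fit)` draws the coefficient
interval plot; `nocturnality()` collapses night + deep night.

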