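# cartrend

Spatially explicit population-trend estimation for route-count surveys
(North American Breeding Bird Survey style) on a longitude/latitude
degree-block lattice.

## The problem and the model

Large-scale bird monitoring programs summarize roadside route counts into
regional population trends. Averaging routes within large reporting
strata ignores two things: route density varies severalfold within a
stratum (sampling imbalance), and abundance changes are spatially
correlated. `cartrend` addresses both by modeling counts at the survey's
own allocation unit — the 1° × 1° degree block — and smoothing across
blocks with an intrinsic conditional autoregressive (ICAR) random field.

The observed count on route *i* in year *t* is Poisson:

    Y_it ~ Poisson(lambda_it),   log(lambda_it) = alpha_t + omega_K(i,t) + b_c(i),t

* `alpha_t` — year intercept, vague N(0, 1e6) prior;
* `omega_k` — observer(-route) random effect, N(0, sigma2);
* `b_c,t` — spatial effect of the degree block containing route *i*'s
  start point, one ICAR field per year: conditionally,
  `b_c | neighbors ~ N(mean of neighbors, tau2 / n_c)` with binary rook
  adjacency, made identifiable by a per-year sum-to-zero constraint;
* `sigma2`, `tau2` — inverse-gamma(0.001, 0.001) hyperpriors.

Fitting is by Metropolis-within-Gibbs MCMC (compiled core, adaptive
random-walk proposals tuned during burn-in only; conjugate Gibbs updates
for the variances), with Gelman–Rubin Rhat diagnostics across chains.

From posterior draws, the expected abundance of a theoretical route in
cell *c* at year *t* is `n_ct = exp(alpha_t + b_ct + sigma2/2)`, and the
trend from year *a* to *b* is the interval-specific geometric mean of
yearly changes, `100 * ((n_cb / n_ca)^(1/(b-a)) - 1)` percent per year,
summarized by the posterior median and central 95% credible interval.

Cell trends aggregate to any reporting region (e.g. a Bird Conservation
Region) by post-stratification: each overlapped cell gets weight
`w'' = w' * A_c / Abar`, where `w'` is the fraction of the cell's
(spherical) area inside the region, `A_c` the cell area
`R^2 (lon2-lon1)(sin lat1 - sin lat2)`, and `Abar` the mean area of the
overlapped cells — degree blocks shrink toward the poles, and the weights
account for it. Aggregation happens per posterior draw, so regional
intervals propagate the full posterior uncertainty.

The package also ships a published 45-comparison BCR trend table
(spatial vs non-spatial method, three species, 1999–2009) as a plain-text
fixture, with functions reproducing its precision-comparison statistics,
and a synthetic-data generator (`simulate_survey()`) that draws data from
the exact generative model with known truth.

## Worked example

```r
library(cartrend)

## synthetic survey: 5x5 degree blocks, 10 years, ~2.5 routes/cell with a
## 3:1 west-east density gradient, observer sd^2 = 0.1, ICAR tau2 = 0.5
sim <- simulate_survey(nx = 5, ny = 5, n_years = 10,
                       sigma2 = 0.1, tau2 = 0.5, seed = 42)
sim$lattice
#> Degree-block lattice: 25 cells at 1 deg resolution ( rook adjacency )
#>   neighbor counts: 2-4  | total area 254663 km^2

fit <- fit_car(sim$data, sim$lattice,
               car_control(n_chains = 3, n_keep = 6000, n_burn = 1000, seed = 1))
fit
#> Spatial trend model fit: 6000 retained draws ( 3 chains x 2000 )
#>   years 1999 - 2008 | 25 cells | 192 observer effects ( observer-route )
#>   posterior medians: sigma2 = 0.0863, tau2 = 0.621
max(convergence(fit))   # Rhat over intercepts and variances
#> [1] 1.015

## trend for one degree block
cell_trend(fit, "-98,34", 1999, 2008)
#> -98,34 1999-2008: -0.45%/yr [-5.33; 4.43] (95% CrI)

## aggregate to a reporting region (any polygon, here a 3x3-degree box)
ring <- cbind(c(-100, -97, -97, -100, -100), c(32, 32, 35, 35, 32))
spec <- region_weights(ring, sim$lattice, "southwest")
region_trend(fit, spec, 1999, 2008)
#> southwest 1999-2008: +1.24%/yr [-1.56; 4.09] (95% CrI)
```

The posterior medians sit close to the generator's truth (`sigma2 = 0.1`,
`tau2 = 0.5`); the cell's 95% interval covers its true trend (−2.83 %/yr
for this cell and seed), and the regional interval is markedly tighter
than single-cell ones — the point of borrowing strength spatially and
weighting cells by area.

The published-table statistics:

```r
tt <- load_trend_table()
count_significant(tt, "CAR")        # 17
count_significant(tt, "nonspatial") # 20
ci_length_sd(tt, "CAR")             # 15.48
ci_length_sd(tt, "nonspatial")      # 26.22
precision_gain(tt)                  # 10 (% shorter CIs, spatial method)
```

A thin CLI over these functions is in `inst/cli/cartrend.R`
(subcommands `simulate`, `fit`, `trend`, `region-trend`,
`table1-summary`); `run_pipeline()` drives the whole
counts → lattice → fit → trends → regions workflow from a single YAML
config.

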