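---
title: "Spatially explicit trends from route-count surveys: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially explicit trends from route-count surveys: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartrend)
```

## The model

`cartrend` estimates population trends from yearly route totals of a
roadside count survey. Each route is reduced to its start coordinates and
assigned to the 1° × 1° degree block (the survey's sample-allocation
unit) containing that point; blocks are half-open,
`[lon, lon+1) × [lat, lat+1)`, so every point belongs to exactly one
block. The count on route $i$ in year $t$ is modeled as

$$Y_{i,t} \sim \text{Poisson}(\lambda_{i,t}), \qquad
\log \lambda_{i,t} = \alpha_t + \omega_{K(i,t)} + b_{c(i),t},$$

with a year intercept $\alpha_t$, a random effect
$\omega_k \sim N(0, \sigma^2)$ for the observer–route combination $k$
(observers differ in detection ability, and the pool of observers changes
over time; without this term observer turnover masquerades as population
change), and a spatial effect $b_{c,t}$ for the degree block $c$, one
field per year so that the spatial pattern of abundance is free to change
through time.

The fields follow an intrinsic conditional autoregressive (ICAR) model on
the block lattice with binary rook adjacency $w_{ck}$ (cells sharing a
boundary segment; corner-sharing "queen" adjacency is available via
`build_lattice(scheme = "queen")`):

$$b_{c,t} \mid B_{-c,t} \sim
N\!\left(\frac{1}{n_c}\sum_k w_{ck}\, b_{k,t},\; \frac{\tau^2}{n_c}\right),$$

i.e. conditional mean equal to the neighbor average and conditional
variance inversely proportional to the number of neighbors $n_c$
(the diagonal scaling $M_c = 1/n_c$). The joint density is the improper
pairwise-difference form of rank $C-1$,

$$\log p(B_t \mid \tau^2) = -\frac{1}{2\tau^2}\sum_{c<k} w_{ck}
(b_{c,t}-b_{k,t})^2 - \frac{C-1}{2}\log \tau^2 + \text{const},$$

made identifiable by constraining each year's field to sum to zero; the
year intercept absorbs the field's level. Small $\tau^2$ means strong
spatial dependence and a smooth surface; large $\tau^2$ lets cells move
independently.

## Priors and defaults

| parameter | prior / default | rationale |
|---|---|---|
| $\alpha_t$ | $N(0, 10^6)$ | vague on the log scale; the data dominate |
| $\sigma^2, \tau^2$ | inverse-gamma$(0.001, 0.001)$ | the long-standing vague conjugate convention for hierarchical count models |
| chains | 3 | enough for between/within Rhat diagnostics |
| retained draws | 20{,}000 pooled across chains | default posterior sample for production fits |
| burn-in | 5{,}000 per chain | discarded; proposal adaptation happens only here |
| adaptation target | 0.44 acceptance | the scalar random-walk optimum |

All are arguments of `car_control()`. The observer effect defaults to one
level per observer–route *pair* (the survey tradition: the same person
can perform differently on different routes); `observer_mode =
"observer"` switches to one effect per person. The retained-draw count is
interpreted as pooled across chains; the manifest written by
`write_draws()` records both the pooled and per-chain counts.

Deliberately **omitted** terms: the non-spatial tradition's start-up
(first-year observer) effect and record-level overdispersion effect. The
spatial model is specified without them, and the generator does not
simulate them; adding an overdispersion term would be the first extension
to consider for real data (see Limitations).

## Sampling and numerical choices

The sampler (compiled, `src/sampler.cpp`) is Metropolis-within-Gibbs:

* scalar random-walk Metropolis for every $\alpha_t$, $\omega_k$ and
  $b_{c,t}$, with per-parameter proposal scales adapted in batches of 50
  sweeps toward 0.44 acceptance **during burn-in only** — freezing the
  scales afterwards preserves detailed balance exactly;
* conjugate inverse-gamma Gibbs draws for $\sigma^2$ (shape
  $a + K/2$, rate $r + \tfrac12\sum_k \omega_k^2$) and for $\tau^2$
  (shape $a + T(C-1)/2$, rate $r + \tfrac12\sum_t \sum_{c<k} w_{ck}
  (b_{c,t}-b_{k,t})^2$) — one shared $\tau^2$ across years, matching a
  single conditional-variance parameter for the whole space–time field
  (the per-year ICAR fields are otherwise independent);
* after each year's field is updated, its mean is subtracted and added to
  $\alpha_t$: the likelihood is untouched and the sum-to-zero constraint
  holds in every retained draw (tested to $10^{-12}$).

Per-record Poisson means are cached and updated multiplicatively on
acceptance (a shift $d$ in one parameter changes the log-likelihood of
its record set by $d\sum y - (e^d - 1)\sum \lambda$); the cache is
refreshed every 500 sweeps to stop floating-point drift.

Initialization: $\alpha_t$ at $\log(\bar{Y}_t + 0.5)$, $\omega$ and $b$
at zero for chain 1 and with N(0, $0.1(\text{chain}-1)$) jitter for later
chains (overdispersed starts make Rhat meaningful), $\sigma^2 = \tau^2 =
1$. A year with no positive counts triggers a warning (its intercept is
only weakly identified by the prior and the spatial field). Everything
runs on R's RNG, so a fixed seed reproduces chains bit-for-bit.

The ICAR model is undefined on a disconnected graph, so
`build_lattice()` applies a connectivity policy: keep the largest
component (default, with a warning), fail (`"strict"`), or `"bridge"`
isolated components to their nearest cell by centroid great-circle
distance. The default cell set is the occupied blocks only; a one-cell
buffer ring (`buffer = TRUE`) is available since unoccupied interior
blocks can help smoothing across gaps — with sparse data either choice is
defensible, and the package exposes both.

`sample_icar_field()` draws exact ICAR fields through the
eigendecomposition of the graph Laplacian (variance $\tau^2/\ell_j$ along
each eigenvector with nonzero eigenvalue), which is also the generative
route used by the synthetic-data module.

## Trend definition

The abundance index for a *theoretical route* in cell $c$ at year $t$ is

$$n_{c,t} = \exp(\alpha_t + b_{c,t} + \sigma^2/2),$$

the mean of $\exp(\alpha_t + b_{c,t} + \omega)$ over the observer-effect
distribution — a new route would come with an unknown observer. Which
variance components enter this retransformation is a genuinely open
choice; `expected_abundance(retransform = "none")` drops the
$\sigma^2/2$ term. The choice is **provably irrelevant for trends**:
within a draw $\sigma^2$ is shared across years, so the factor
$e^{\sigma^2/2}$ cancels in the ratio $n_{c,b}/n_{c,a}$ (verified to
$10^{-12}$ in the tests). It matters only for reported abundance levels.

The trend from year $a$ to $b$ is the interval-specific geometric mean of
yearly changes, expressed as a percentage:

$$T_c = 100\,(B_c - 1), \qquad B_c = \left(\frac{n_{c,b}}{n_{c,a}}\right)^{1/(b-a)}.$$

It is computed per retained draw and summarized by the posterior median
(the mean is available via `point = "mean"`) and central 95% interval
(type-7 percentiles). Per draw, trends chain exactly across subintervals,
are invariant to rescaling all abundances, and always exceed −100%.

## Post-stratification

A region's trend is the weighted average of its cells' per-draw trends
with weights $w''_{ck} = w'_{ck} \cdot A_c / \bar{A}_k$: the overlap
proportion $w'$ corrected by the cell's spherical area relative to the
mean area of overlapped cells. Cells are latitude–longitude rectangles,
so their exact area on a sphere of radius $R$ (6371 km by default;
configurable) is $A = R^2(\text{lon}_2-\text{lon}_1)(\sin\text{lat}_1 -
\sin\text{lat}_2)$.

Overlap proportions are computed by clipping the region polygon to the
cell rectangle in lon/lat coordinates (Sutherland–Hodgman) and measuring
the clipped piece with the spherical area element $R^2\cos\phi$ via a
Green's-theorem line integral with closed-form edge terms. This treats
polygon edges as straight lines in lon/lat space — exact for the cell
geometry itself and consistent with the area formula above; for typical
region polygons with many vertices the deviation from great-circle edges
is negligible at degree scale. Polygons crossing the antimeridian must be
pre-split at ±180° (the GeoJSON convention); the package does not stitch
them.

Aggregation is per posterior draw by default, so the regional trend is a
convex combination of member-cell trends draw by draw and its credible
interval reflects the joint posterior, including cross-cell correlation.
`mode = "point-estimate"` instead averages the cells' posterior medians —
useful for comparison with workflows that aggregate published point
estimates, but it has no honest interval and is not the default.

## The synthetic-data generator

`simulate_survey()` draws data from exactly the model above: routes
placed uniformly within their block, with per-cell route counts
`1 + Poisson(mu - 1)` along a west–east linear density gradient whose
max/min ratio is configurable (real surveys show around 3-fold or larger
density differences between regions; the floor of one route per cell
keeps every block occupied); observers assigned per route with geometric
turnover (default 0.15/year, a multi-year median tenure as in volunteer
surveys); one ICAR field per year; Poisson counts. Default year
intercepts start at about 10 birds per route and decline about 2% per
year — a typical songbird scale.

What it deliberately does **not** emulate about real survey data: missing
route-years (every route is surveyed every year), start-up effects,
extra-Poisson dispersion, detection covariates such as weather, and range
edges (every cell has routes). Passing the recovery tests therefore shows
the estimator is correct and calibrated *under the model's own
assumptions* — it does not certify robustness to the misspecifications
real data bring.

## Verification scale and what the tests show

The test suite checks the primitives against independent oracles (dense
Gaussian conditioning and quadrature for the ICAR conditionals, numerical
integration for spherical areas, closed forms for trends and weights) and
runs a replicated end-to-end recovery: a 6×6 grid over 10 years with a
3:1 route-density gradient, $\sigma^2 = 0.1$, $\tau^2 = 0.5$, fit with 3
chains × 3,000 iterations (1,000 burn-in), 20 replicates. These sizes
keep a full fit to a few seconds while leaving the variances and trends
well-identified; across replicates the 95% intervals cover the true
variances and ≥ 90% of true cell trends, with all Rhat < 1.1.
`scripts/acceptance.R` re-runs a 10-replicate version of the same harness
from scratch and writes the coverage summaries, alongside the
precision-comparison statistics recomputed from the shipped BCR table.

On that table: significance counts treat a printed CI bound of exactly 0
as excluding 0 (`zero_bound_excludes = TRUE`), since printed bounds are
rounded; all statistics are computed from the printed values, which is
why the row-wise "shorter CI" count is reported but only its tie count is
a stable quantity — unrounded internal values would be needed for the
rest.

## Known limitations

* No overdispersion term: real counts are noisier than Poisson, and the
  model will attribute excess noise to the observer and spatial terms.
* Trends for cells with no data in the interval's endpoint years lean
  entirely on the spatial prior; their intervals are honest but wide, and
  at range edges estimates are shrunk toward neighbors.
* The sampler updates parameters one at a time; for very large lattices
  (thousands of cells × decades) block updates or sparse-matrix samplers
  would mix faster per second.
* Region geometry assumes lon/lat polygon edges; regions defined in
  projected coordinates must be converted first.
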