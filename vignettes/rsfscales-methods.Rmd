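---
title: "Multi-scale resource selection with risk-allocation hypothesis sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale resource selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

A stationary prey species living in confined home ranges cannot escape risk
by ranging widely: it must *place* its range well (second-order selection)
and then *use* the range selectively in space and time (third-order
selection). Where a strictly protected core area adjoins multi-use land,
risk has two faces — natural predation inside, human disturbance plus
residual predation outside — and prey may respond to risky *places*
(spatially differentiated selection inside versus outside the core), risky
*times* (diel and circalunar modulation), or allocate between the two.
`rsfscales` implements the full analysis pipeline for testing these
hypotheses on GPS telemetry: covariate derivation, two-level use-availability
sampling, binomial mixed-model fitting of named hypothesis structures,
AIC-based multi-model inference with a set-support statistic, k-fold
validation of the fitted selection functions, hourly split models with
raised-cosine diel regression, lunar-interaction extraction, and an
individual-level functional-response test.

Because telemetry data of this kind are rarely redistributable, the package
ships a synthetic landscape-and-track generator with *known* selection
coefficients. Every stage of the pipeline is tested by parameter recovery
against that generator rather than against external data.

# The model

## Use-availability resource selection functions

Used points (relocations, or range points for the placement analysis) are
contrasted with available points (uniform random draws from the choice set)
in a binomial logistic mixed model. The exponential of the fitted linear
predictor is the resource selection function (RSF), proportional to the
relative probability of use. Five spatial covariates enter throughout:
woody cover (`WC`, %), focal Shannon vegetation diversity (`SVD`), seasonal
NDVI, proximity to water (`ProxW`, metres — note *larger = farther*), and
the terrain ruggedness index (`TRI`).

At the **landscape level** the choice set is the study region: available
points are uniform over the region, used points are a 10% subsample of
random points inside the individuals' 100% minimum convex polygons (MCPs),
so the contrast captures where ranges sit in the landscape. At the
**home-range level** the choice set is each individual's MCP: available
points are uniform within MCPs (counts proportional to each individual's
relocations), used points are a 1/24 subsample of the relocations. The
available total is `round(10 * n_relocations / 24)` — ten times the mean
hourly relocation count — giving the design's approximate 1:10
used:available ratio at both levels.

## Hypothesis structures

Thirteen named fixed-effect structures encode the risk-coping hypotheses.
The suffix picks covariates — `f` (forage: WC + SVD + NDVI), `r` (risk:
WC + ProxW + TRI), `fr` (both) — and the prefix picks the modifier: `G`
(generic, none), `S` (crossed with the two-level inside/outside-core factor
`InOut`), `T` (crossed with moon illumination), `ST` (crossed with both).
A woody-cover-only model `0` serves as the null. Temporal structures are
meaningful only where rows carry timestamps, so the landscape level uses
the seven atemporal structures and the home-range level all thirteen.
All models carry random intercepts for management area and individual;
home-range (and hourly) models additionally carry year and season nested in
year, coded as the year factor plus the year-by-season combination factor.

Continuous covariates are z-scored on the pooled used+available rows (the
fit stores the scaling and also reports back-transformed per-raw-unit
coefficients); moon illumination enters as percent/100; `inside` is the
reference level of `InOut`. Degrees of freedom are counted as
`n_fixed + n_variance_components` and `AIC = -2 logLik + 2 df`.

## Delta-AIC-ratio set support

Models are ranked by AIC. Support for a named *set* of structures (all `S`
models, all `fr` models, ...) is summarised by the delta-AIC-ratio: the
mean delta AIC across all hypothesis models divided by the mean delta AIC
within the set, so values above 1 indicate above-average support. The null
model is excluded from both means. That exclusion is not an arbitrary
choice: with the bundled published parsimony table
(`serengeti_parsimony()`), excluding the null reproduces every one of the
ten printed ratios to two decimals, while including it reproduces none —
the package codifies this as a regression test. Ratios recomputed from the
integer-rounded printed table can differ from ratios computed on unrounded
AICs in the last digit (the printed S-set ratios are 1.45/1.39 where the
rounded table yields 1.44/1.40); tests therefore use a +-0.01 tolerance.

## Cross-validation (area-adjusted frequency rank correlation)

Predictive success is measured with k-fold cross-validation adapted to RSFs:
rows are binned at random into k classes (stratified by the response), the
model is refitted without each class, and held-out rows are scored by the
fixed-effect linear predictor with random effects at their population mean
(held-out groups may be unseen, and the fixed part is the portable
component of an RSF). Held-out scores are cut into ten bins whose edges are
quantiles of the held-out *available* scores (equal available count —
degeneracy-resistant; equal-width bins are available behind a flag), and
each bin's area-adjusted frequency is the used share divided by the
available share. The Spearman correlation between bin rank and adjusted
frequency is reported per fold, with Fisher's method combining fold
p-values. A well-specified RSF gives mean rho near 1; a signal-free one
gives mean rho near 0. Spearman makes the statistic invariant to monotone
transforms of the linear predictor (tested).

Two sample-size caveats matter when interpreting rho. First, the
landscape-level model predicts *range placement*, so its effective sample
size is the number of individuals, not the number of rows: with a handful
of simulated ranges the landscape RSF cross-validates weakly no matter how
well it is specified. Second, the adjusted frequency of a bin is a ratio
of counts; with fewer than ~10 held-out used rows per bin its noise alone
caps the achievable rank correlation well below 1.

## Diel and lunar analysis

Diel patterns are analysed by *split modelling*: the selected home-range
structure is refitted 24 times, once per hour of day, each time contrasting
that hour's relocations with the full MCP availability. This avoids both
temporal autocorrelation within hours and a 24-way interaction in a single
model. Each covariate's (and each side's, inside/outside) 24 hourly
coefficients are then regressed by OLS on fixed raised-cosine templates:

* single (day/night): `r1(h) = (1 + cos(2 pi (h - 12) / 24)) / 2`, peak at
  noon, trough at midnight;
* double (dawn/dusk): `r2(h) = (1 + cos(2 pi (h - 6) / 12)) / 2`, peaks at
  06:00 and 18:00.

The template phases (noon; 06:00/18:00) are configuration defaults chosen
to match the day/night and dawn/dusk interpretation of the two patterns.
The two templates are exactly orthogonal harmonics over the 24 equispaced
hours, so an injected single-harmonic signal loads only on its own template.
The F statistic (df 1, 22 with all hours present) is invariant to affine
rescaling of the template, so whether a "raised" cosine spans [0, 1] or
[-1, 1] is immaterial — both facts are tested. OLS is unweighted by
default, with an optional 1/variance weighting by the hourly within-model
variances. Regressors are evaluated at the integer hour; an `h + 0.5`
evaluation would only rephase the templates and is not used.

Circalunar response is read off the `covariate:moon` interactions of the
temporal structures; `lunar_interaction()` extracts the coefficient and
builds the predicted relative-selection curve over 0-100% illumination
(at 0% the curve reduces to the main effect alone, by construction).

## Functional response

For each individual, covariate and level, the selection ratio is the mean
covariate value at used points over the mean at available points (landscape
availability pooled across individuals; home-range availability restricted
to the individual's own MCP points; an individual's landscape-level "use"
is its share of the MCP random points, mirroring the level definitions).
Proximity-to-water ratios use the raw distance, so values above 1 mean
*farther from water than available*. The functional-response test is the
Pearson correlation across individuals between the two levels' ratios,
computed separately for individuals classified inside or outside the core
(majority of their home-range used points; the study design does not say
how straddling individuals should be classified, so the majority rule is
used and logged). A negative correlation means within-range selection
weakens as landscape-level exposure rises.

# The synthetic world

## What it emulates

`generate_landscape()` builds spatially autocorrelated fields on a common
projected 30 m grid (configurable): percent woody cover, a DEM (from which
TRI is derived), a 5-class land-cover map (from which focal Shannon
diversity is derived over a 1 km buffer), four seasonal NDVI layers, and a
rasterised river network (from which proximity to water is derived by an
exact distance transform). A protected core occupies the western 55% of the
extent; the remainder is tiled into three management-area strips, so
points and range centres always fall in exactly one area.
`moon_series_synthetic()` supplies daily percent illumination from the
idealised circalunar cosine `50 (1 - cos(2 pi t / 29.53 d))`.

`simulate_tracks()` realises a point-process RSF: range centres are drawn
with probability proportional to `exp(beta_landscape . x)` of
kernel-smoothed local covariates, stratified so half the individuals sit
inside and half outside the core (with few simulated individuals an
unstratified draw can leave one side empty, making the `InOut` structures
inestimable); given a centre, hourly fixes are independent draws from the
cells of the home-range disc with weight `exp(b(t) . x)`, where

```
b(t) = beta_within
     + delta_outside * [point outside core]
     + diel_single  * r1(hour)  + diel_double * r2(hour)
     + lunar * moon_pct(t) / 100
```

Tracking starts are staggered over a 1.2-year window (so the year and
season-in-year factors have multiple levels even in scaled runs), fixes are
hourly, and the MCP is recomputed from the realised points exactly as for
real data.

Defaults mirror the emulated study's data shape: 36 individuals, ~5,000
hourly fixes each, and a home-range scale (sigma 750 m, disc radius 3 sigma)
whose 100% MCPs land near the reported ~16 km^2 median. Tests and the
acceptance experiments run a scaled condition (8 individuals x 1,000 fixes
on a 14 x 14 km landscape at 100 m cells, home-range scale at its default)
so the full suite stays within a normal CI budget; the statistical
structure is unchanged. The well-specified cross-validation check uses a
larger single run (16 individuals x 3,000 fixes on 16 x 16 km): the
area-adjusted frequencies need enough held-out used rows per score bin
(tens, not units) before the bin-rank correlation can be expected to
approach 1, and the recovery-sized runs leave only ~3 used rows per bin
per fold.

## Generative choices that matter

* **Uniform-base home ranges.** The home-range kernel truncates at
  `trunc * home_range_scale`, and within that disc the base density is
  *uniform*, so used points are distributed exactly as
  `exp(b . x)` against uniform availability — the model the pipeline fits.
  A centre-weighted Gaussian base is available
  (`truth_config(kernel = "gaussian")`), but its radial density gradient is
  an omitted variable for the RSF likelihood and attenuates recovered
  coefficients; it is off by default precisely because the generator's job
  here is exact likelihood-based recovery, not maximal behavioural realism.
* **Independent draws.** Fixes are conditionally independent given the
  range, matching the RSF likelihood; real hourly telemetry is serially
  correlated, so passing recovery tests here says nothing about
  autocorrelation-robustness on real data.
* **Effect sizes.** Where the emulated study reports no generative values,
  the defaults were sized once by a power analysis of the design itself:
  the 1:10 / 1/24 sampling rules fix ~333 used rows in the scaled
  condition, giving standard errors of ~0.12 (mains) and ~0.25 (InOut
  interactions) per landscape SD, so "moderate, detectable" means mains of
  0.35-0.5 SD and active interaction shifts of 0.5-0.6 SD. TRI carries
  less realised within-range information than the smoother covariates, so
  its truth values sit at the upper end of that range to equalise realised
  Wald statistics across covariates.
* **Small seasonal NDVI offsets.** Seasonal layers differ mostly in
  spatial pattern, with small seasonal mean shifts (+-0.03-0.07). This is
  deliberate: none of the hypothesis structures contains fixed seasonal
  terms, and under the ratio-matched sampling design the per-season
  used:available ratio is constant by construction, so the season-in-year
  variance component cannot pick up season-level intercepts — it estimates
  to zero and any seasonal *mean* shift in NDVI attenuates the NDVI slope
  by `var_spatial / (var_spatial + var_offset)`. With large seasonal
  swings (realistic for savanna NDVI) the same attenuation would affect a
  real analysis using these model structures; that is a limitation of the
  design worth knowing, not something the generator should hide recovery
  problems behind.
* **Moon discretisation.** The sampler groups fixes by (season, hour, moon
  rounded to 5%) for speed; the analysis side always uses the exact daily
  value. The residual attenuation of lunar coefficients is negligible
  relative to their standard errors at tested sizes.

## What passing the tests does and does not show

Parameter recovery, model-selection behaviour, cross-validation bounds and
diel detection rates demonstrated on this generator validate the *code* and
the *statistical identities* of the pipeline under a well-specified world.
They do not establish robustness to serial correlation, location error,
behavioural heterogeneity between individuals, herd effects, or seasonal
availability shifts — all absent from the generator by design.

# Sampling-design conventions

* Hour of day is local solar time at a fixed UTC+3 offset, floored to the
  integer hour; a 13:59 fix belongs to the h = 13 table.
* Available rows at the home-range and hourly levels need temporal metadata
  (hour, season, year, moon) for the temporal structures and grouping
  factors; each available row draws a timestamp from its own individual's
  relocations (within the hour, for hourly tables), which matches the
  marginal temporal distribution of use. Their NDVI follows the
  season at the midpoint of the individual's tracking period by default,
  with `ndvi_available = "timestamp"` as the alternative; the recovery
  experiments use the timestamp convention because the midpoint convention
  deliberately misstates seasonal availability (it is the simpler field
  convention, kept as the default for the pipeline).
* Landscape rows carry no timestamps; NDVI there is the across-season mean
  layer. Available landscape rows are assigned an individual id in
  proportion to relocation counts so the individual random intercept is
  defined on every row.
* Points on polygon boundaries count as inside (closed polygons). Points
  on nodata background are dropped and counted, never resampled.

# Numerical choices

* Focal class counts use FFT convolution with a centre-inclusion circular
  kernel (a cell belongs to the buffer iff its centre is within the radius);
  counts are rounded to integers to remove FFT noise before proportions are
  formed, and a fractional-area weighting is available behind a flag.
  Shannon diversity uses the natural logarithm.
* TRI at edges uses the available neighbour subset, so the index is defined
  to the grid edge.
* Proximity to water is the exact Euclidean distance transform
  (two-pass parabolic envelope), checked against a brute-force nearest-cell
  scan in tests.
* Bilinear resampling clamps at the outermost cell centres; categorical
  layers resample by nearest neighbour.
* Mixed models are fitted by Laplace-approximated ML (`lme4::glmer`,
  bobyqa optimizer, derivative checks off for speed); fits are
  deterministic given data and optimizer. Non-convergence is flagged on
  the result, and variance components at the zero boundary set a
  `singular` flag — expected and benign when the generative truth has no
  group-level noise. An independent single-factor 25-node adaptive
  Gauss-Hermite oracle and a plain-logistic boundary oracle guard the
  engine in the test suite.
* Quantile bin edges that collide (tied scores) are merged and flagged;
  the outer bin edges are extended to +-Inf so held-out scores outside the
  training range still bin.
* AIC ties are broken toward fewer degrees of freedom and flagged.

# Known limitations

* Grids are in-memory dense matrices; extents beyond ~10^7 cells are out of
  scope (the emulated study's 30 m grids over ~200 x 75 km would need a
  tiled backend).
* GeoTIFF I/O is not provided; rasters exchange as ESRI ASCII grids and
  vectors as GeoJSON/CSV.
* The raised-cosine machinery assumes 24 hourly bins; other binnings would
  need new templates.
* Step-selection designs, random slopes, weighted RSF likelihoods and
  spatially blocked cross-validation are out of scope.
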