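---
title: "Methods: land use regression modelling of urban noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land use regression modelling of urban noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiselur)
```

This vignette documents the models the package implements, the conventions
and defaults behind them, what the synthetic-city generator does and does
not emulate, and the design decisions taken where reasonable alternatives
existed.

## Acoustic metrics

All averaging of decibel levels is **energetic**: a set of levels is
summarised as `10 log10(mean(10^(L/10)))`, the equivalent continuous level
(LAeq) carrying the same acoustic energy. This applies at every stage:
minutes into hours (`hourly_levels()`), days into the long-term hourly
profile (`hourly_profile()`), and hours into the period metrics
(`period_metrics()`). Arithmetic dBA means appear in exactly one place —
enumeration-area averaging — discussed below.

Clock conventions follow the Ghana Standards Authority day definition:
day 06:00–21:59 (16 h), night 22:00–05:59 (8 h). L_den splits the day
block further into day 06:00–18:59 (13 h) and evening 19:00–21:59 (3 h),
and penalizes evening energy by +5 dBA and night energy by +10 dBA before
the 24 h energy average. Two consequences are used as test oracles: a flat
profile at X dBA has `L_den = X + 10 log10((13 + 3·10^0.5 + 80)/24) =
X + 6.305`, and L_den can never fall below LAeq_24hr while night or
evening hours carry energy. Hours are half-open local clock hours; Ghana
is UTC year-round with no daylight saving, so no timezone arithmetic is
performed. Hours with zero logged minutes are omitted, not imputed, with
`n_minutes` recording completeness.

**Long-term hourly averages are energetic across days.** Whether such
averages should be energetic or arithmetic is a genuine convention choice;
the energetic mean is consistent with equivalent-continuous-level
semantics (the annual-average hour carries the mean energy of that hour
across days), so it is used throughout. With day-to-day hourly variation
of a few dBA the two differ by a few tenths of a dBA.

**Intermittency ratio (IR).** For a period (day or night), the threshold
is K = LAeq_period + 3 dBA and IR is the percentage of the period's total
energy carried by minutes with level ≥ K. Events are defined per minute —
no reconstruction of events spanning adjacent samples is attempted,
because at 1-minute integration the sub-minute temporal structure is
already lost; a finer event-tracking definition exists for 1 s data but
cannot be reproduced at this resolution. The +3 dBA offset is
configurable (`offset_c`); stricter cutoffs give lower IRs.

## The mixed-effects LUR model

Hourly levels are modelled as

`L_sh = β0 + Σ_k β_k x_ks + γ·height_s + a_h + b_s + ε_sh`

with crossed random intercepts for hour of the day and site, estimated by
lme4 (REML for reported models; ML during selection, where only the
fixed-effect R² is consulted). Monitor height (m above ground, ~4 ± 1 m)
is always included as an adjustment covariate and is never subject to
selection or pruning. Day and night models are fully separate fits.

**R² definition.** Mixed models have no single R². The selection
criterion used here, `r2_fixed`, is the squared Pearson correlation
between fixed-effect predictions and observed hourly levels; a marginal
variance-partition R² (`var(Xβ) / (var(Xβ) + σ²_site + σ²_hour + σ²_res)`)
is reported alongside for transparency. Confidence intervals are Wald
(estimate ± 1.96 SE), adequate at 140 sites × thousands of hourly rows.

**Screening (step one).** Bivariate correlations are computed against the
*site-level period LAeq*, not hourly rows — hourly rows would
pseudo-replicate each site ~100-fold and overstate significance without
changing the ordering. Per variable, the buffer with the largest |r|
wins; ties within 1e-6 go to the smaller buffer (more local, more
interpretable). Variables whose sign contradicts the a-priori expectation
are excluded while the sign constraint is on. The expected-sign list
follows LUR convention: road, building, POI and population variables
positive; NDVI and formal-residential area negative; road distances
negative; airport and water variables unconstrained (`either`).

**Stepwise (step two).** Starting from the intercept + height model,
forward addition of the candidate with the largest `r2_fixed` gain,
stopping when the best gain is below 0.01 ("no longer improved by at
least 1%"). Then: stability pruning; a challenge round where every
excluded candidate is re-offered one at a time (adopted on a gain ≥ the
same 0.01 threshold — the literature does not pin the challenge
criterion, so the entry threshold is reused); and a collinearity filter
that, for any selected pair with |r| > 0.8, keeps the member more
correlated with the outcome. Candidates that would make the design
singular simply cannot enter. Every decision lands in the selection
trace, and selection is deterministic given data and candidate order.

**Stability rule.** The qualitative rule "large coefficient with a large
interval is unstable" is quantified as: drop a variable iff its 95% CI
crosses zero *and* |t| < 1 (the CI half-width exceeds the coefficient
magnitude). A modest coefficient whose CI crosses zero but with |t| ≥ 1
is retained — population density with a CI like [−0.4, 2.0] around 0.8
survives, an erratic 0.1 [−2.0, 2.2] does not. The t threshold is
configurable (`stability_t`).

**IR models.** Site-level IRs are modelled with ordinary least squares
through the same two-step machinery (IR is one number per site and
period, so there is no hour random effect). The period noise level
(L_day or L_night) joins the candidate list at its bivariate strength.
The a-priori sign constraint is **off** for IR models: steady heavy
traffic *lowers* intermittency, so noise-LUR sign expectations do not
transfer. After selection, an interaction of the noise-level term with
the site's land-use class is evaluated post hoc; with a single
represented class it is dropped with a warning.

## Evaluation

Cross-validation folds partition **sites**, never rows: held-out sites
are entirely unseen, and predictions use fixed effects plus the
training-set hour intercepts but no site intercept — exactly the
situation of predicting at an unmonitored location. Hour intercepts are
included because they are estimable from training data. The final
variable set is refit per fold by default (the common LUR practice);
`reselect = TRUE` re-runs the whole selection inside each fold for a
stricter audit. Pooled metrics are computed over all held-out
observations, not averaged over folds. Feature standardization parameters
are fitted once on all sites and reused across folds; refitting them per
fold changes held-out features by fractions of an SD and is immaterial at
these sizes.

Moran's I uses row-standardized inverse-distance weights with no distance
cutoff and a seeded permutation test (999 permutations by default);
under exchangeability E[I] = −1/(n−1). The implementation is validated in
the tests against a brute-force double-loop oracle and against
`ape::Moran.I` on the same weight matrix.

## Surfaces and exposure

Prediction grids default to 50 m cells at a fixed monitor height of 4 m.
Cells are masked out when they touch water, or when their land-cover
class (read at the cell center) is 'other' (grassland/forest/bare) *and*
no road of any class crosses the cell — predictions there would
extrapolate beyond anything the sites represent. Partially vegetated
cells with a road are masked in.

Each of the 24 hourly surfaces uses the day model (hours 6–21) or night
model (hours 22–5) with that hour's fitted intercept — hour intercepts
enter grid predictions because the product is explicitly 24 distinct
hourly surfaces. Aggregate layers are computed per cell by the same
`period_metrics()` used for sites, so the aggregation identity holds
*exactly* and is asserted in the tests.

**Enumeration-area averaging is arithmetic on dBA** (an `energetic = TRUE`
variant exists). Area exposure summaries conventionally average the
spatial distribution of a level surface rather than its energy; on smooth
surfaces the two differ by well under a dBA. Whole-EA populations are
assigned to the 5 dBA bin of the EA-mean level (no within-EA dasymetric
allocation). Guideline exceedance uses strict inequality against L_den 53
/ L_night 45 dBA. SES quintiles are contiguous rank groups with sizes
differing by at most one EA and ties broken by stable EA id; correlations
carry Fisher-z 95% CIs; the bottom-vs-top quintile comparison is a Welch
(unequal-variance) two-sample test — the natural default when group
variances are unknown. Only the extreme quintiles are compared; adjacent
comparisons can be run by subsetting.

## The synthetic city

The generator emulates, at desk scale, the data a metropolitan noise
campaign consumes. Defaults: a 4 × 4 km extent (a real metropolitan area
is far larger; all operations take extent and resolution from
configuration), a 20 m land-cover raster in four classes
(industrial/commercial, informal high-density residential, formal
low/medium residential, other), 30 m NDVI negatively coupled to road
proximity, a 90 m DEM, three road classes, eight POI categories, building
centroids, an airport polygon, a lake, and 40 enumeration-area polygons
that partition the extent, carrying populations (densities by dominant
land cover: roughly 15,000 / 6,000 / 2,500 / 400 people/km² for informal,
formal, industrial and other) and SES measures with wealth increasing
away from arterials. 146 sites (136 rotating, 10 fixed) mirror a
stratified campaign: rotating sites get 7 simulated days and fixed sites
30 — enough to preserve the unbalanced design without year-long logs.
Stratification is on land-cover class alone (proportional to class area);
the additional population weighting a real campaign might use is not
modelled.

The ground truth is the same linear model the package fits: default
coefficients of +2.5 (major roads, 100 m), +1.8 (secondary/tertiary,
200 m), −0.8 (formal residential, 200 m), −2.8 (NDVI, 50 m) and +0.8
(population density, 500 m) dBA per SD on a 60 dBA intercept, site
intercept SD 2 dBA, minute residual SD 3 dBA, and Poisson sound events
(2/h, +12 dBA energetic gain per event minute). The diurnal profile has
morning/evening peaks and a night trough with the day block ~7 dBA above
the night block. One deliberate asymmetry: the hour effects are *not*
centered within the day and night blocks — centering both blocks would
force L_day ≈ L_night and erase the day–night structure the surfaces must
reproduce, so the block difference is kept as generative structure.

What passing tests on this city do **not** show about real data: the
truth is exactly linear in the fitted features (no propagation physics,
street canyons, barriers or reflections), there is no weather, no traffic
microsimulation, no measurement error beyond Gaussian noise and Poisson
events, geometries are simple (straight road segments, rectangular EAs
and water bodies), and the feature set used for generation is a subset of
the candidate set. Recovery results validate the *machinery* —
estimation, selection, cross-validation, aggregation accounting — not the
adequacy of linear LUR for any particular city.

## Numerical choices and degenerate inputs

- Buffers are closed disks; boundary features count (deterministic ties).
- Raster zonal statistics use cell-center-in-disk inclusion at the
  raster's native resolution; NDVI means omit negative (water) cells;
  population density in a buffer is the area-weighted mean of
  intersecting EA densities, implemented via a density raster at
  land-cover resolution.
- Standardization uses the sample (n−1) SD; parameters are fitted on the
  site set and reused verbatim for grids and CV folds; a parameter
  mismatch at prediction time is a hard error. Count and presence
  variables stay on their raw scale. Zero-variance columns are excluded
  with a warning.
- Empty candidate lists produce an intercept-only model with a warning;
  constant outcomes yield R² = 0 rather than NA; aliased terms are
  dropped from OLS fits; perfect collinearity reports infinite VIF.
- Pipeline child seeds are the run seed plus small fixed offsets, so
  stages are independently re-runnable and every artifact is
  reproducible from the config seed.

## Problem sizes

The validation suite runs the campaign-scale configuration (140 sites ×
7 days, ~1.4 M simulated minutes per replicate) for coefficient recovery
(50 replicates), selection (30 replicates, 3 active + 7 inert
candidates) and LOOCV calibration, and smaller cities (≤ 50 sites) for
unit-level properties; the acceptance script uses 10 replicates per rate
at the same campaign scale. These sizes were chosen so a full validation
run completes on a laptop in minutes while leaving the replicate counts
large enough for the rate thresholds (80–90%) to be meaningful.

## Known limitations

- Noise propagation is not modelled; the package predicts what a linear
  LUR can represent.
- The IR at 1-minute integration under-counts short events by
  construction.
- GeoJSON and ASCII-grid writers cover the package's own layers
  (segments, rectangles, single-band rasters); they are interchange
  formats for inspection in a GIS, not a general-purpose spatial IO
  layer.
- EA polygons are rectangles from a structured partition; real census
  geographies are irregular, which mainly affects edge-cell assignment
  in `ea_average()`.
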