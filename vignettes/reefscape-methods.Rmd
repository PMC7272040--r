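---
title: "Methods: habitat structure metrics and herbivorous fish models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat structure metrics and herbivorous fish models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reefscape` quantifies the structure of coral-reef habitats from
one-dimensional elevation cross-sections and relates it to the distribution
of roving herbivorous fishes. This vignette documents the models, the
numerical choices, and the design decisions behind each stage, and states
what the synthetic-data experiments do and do not demonstrate.

## Cross-sections and the six metrics

All structural metrics operate on an `reef_profile`: ordered samples
`(x, z)` in metres along a 5 m transect. Profiles are single-valued
functions `z(x)`; true undercut overhangs cannot be represented, which is
why overhangs are proxied by near-vertical surfaces (cross-sections from
photogrammetric models share exactly this limitation).

- **Rugosity** is the virtual chain-and-tape index
  `RI = L_chain / D_chain`, with the contoured length summed as
  `sqrt(dx^2 + dz^2)` over consecutive samples. `RI = 1` iff the profile is
  flat; the measure is additive over any partition of the transect (range
  endpoints are interpolated linearly, never snapped).
- **Verticality** resamples the profile linearly on a grid of 10 cm
  intervals anchored at `x = 0` and averages `|Δz| / 0.1`. Anchoring at the
  transect start makes the metric reproducible and gives exactly 50
  intervals on a 5 m transect; a trailing partial interval is dropped. The
  10 cm scale matches the body size at which reef fishes engage with
  structure.
- **Cover fractions** (hard coral, grazing surface area) weight each
  benthic interval by its *contoured* length, so a category draped over
  steep relief counts more than its planar footprint. Segmentations use
  half-open intervals `[start, end)`; fractions over a label partition sum
  to one. Grazing surface area counts only the `turf_EAM` category —
  short algal turfs on consolidated substratum; macroalgae is excluded
  because few roving herbivores feed on it, as are sand and live coral.
- **Refuge density** pools two detections sized by a 10 cm disc (a fish's
  cross-section). *Crevices* are notches whose rim opening width lies in
  10–20 cm, whose depth is ≥ 10 cm, and into which the disc fits without
  intersecting terrain. Candidate floors are points whose two-sided local
  prominence (within a 25 cm window) reaches the 10 cm depth rule; each
  candidate's notch is delimited by the highest water level at which the
  flooded region stays no wider than the maximum crevice width, and the
  opening width is measured at that level — the shallower rim shoulder.
  This level-set construction keeps a conforming notch detectable even when
  it sits inside a broader depression on rough terrain. Two crevices closer
  than the gauge diameter merge into one candidate, because a single disc
  placement cannot distinguish them. *Overhangs* are maximal monotone runs
  with inclination ≥ 80° (configurable) and vertical extent ≥ 10 cm that
  are not walls of a counted crevice.
- **Feeding field of view** places observer eyes 2.5 cm above the benthos
  every 1 m from 0.5 m; each looks horizontally toward the transect
  midpoint, the exact midpoint observer looking both ways (its two
  directions are averaged, so every observer location carries equal
  weight). The obstruction angle is the maximum angle above horizontal
  subtended by any terrain sample within the 2.5 m sight length — the
  physically blocking sample, which coincides with the "highest point
  touched by the secant" except when a nearer, lower feature subtends more;
  the max-angle reading is adopted as the physically defensible one.
  Downward angles clamp to zero: a fish looking over a drop-off keeps its
  full upward view. Per-observer visibility is `(90 − θ)/90` of the upward
  quadrant (no solid-angle weighting), and the transect score is the mean
  over observers. The *visible* fraction is the quantity carried into
  downstream models; the blocked fraction is always co-reported as its
  complement.

`sample_transect_from_dem()` extracts profiles from a gridded elevation
model by bilinear interpolation, with out-of-bounds endpoints and no-data
cells raising named errors.

## Tides and accessibility

Tide heights between consecutive extremes follow the mariner's Rule of
Twelfths, implemented literally: six equal sub-intervals with cumulative
range fractions (1, 3, 6, 9, 11, 12)/12 and linear interpolation inside
each. The rule deviates from a true sinusoid by at most ~2.6% of the tidal
range; a cosine comparison is kept as a test oracle but never used in the
implementation. Depth soundings are converted to benthos levels relative to
the tide datum (`benthos = tide_height(t) − depth`), which makes the result
independent of when the sounding was taken.

Accessibility is the percentage of time a habitat carries at least 30 cm of
water — the depth that admits roving herbivores; depth exactly at the
threshold counts as accessible, matching the exclusion rule "covered by
less than 30 cm". It is evaluated on a 10-minute grid by default; halving
the step moves the result by well under 0.1 percentage points over a
synthetic year. One numerical subtlety is documented in the tests: at a
threshold crossing the piecewise-linear interpolant's height error
translates into a crossing-time error, so agreement with the arccos
closed form for a sinusoidal tide is exact (to grid precision) only at
crossing heights where the rule coincides with the sinusoid (cumulative
3/12, 6/12, 9/12); at generic phases the discrepancy is bounded near 2
percentage points. The acceptance checks therefore pin the closed form at
the rule-exact heights and bound generic phases separately. Grid steps
commensurate with the tidal period would alias the crossings, so tests use
incommensurate steps.

## Fish surveys

Censuses record counts per species and total-length class on two belts: 5 m
wide for fishes > 10 cm TL (5 cm classes) and 1 m wide below (2.5 cm
classes). Each belt is standardised to 250 m² separately before summing, so
the narrow belt's counts are up-weighted fivefold — the convention adopted
for pooling the two belts. Replicate census days are averaged per
site × habitat unit, not pooled as extra observations. Biomass uses the
size-class midpoint (the conventional choice for lengths uniform within a
bin) through `W = a·L^b` with user-supplied length–weight parameters; no
live database lookup, keeping the package fully offline.

## Hierarchical habitat models

Every among-habitat comparison fits
`response ~ habitat + (1 | site)` with a means parameterisation. Families
follow the response's support: Gaussian for continuous metrics, a beta
regression with logit link and precision parameter for proportions
(continuous contour fractions are not binomial counts, so a beta family
with the +0.001 boundary offset is the faithful continuous analogue of an
overdispersed proportion model; offset values reaching 1 are compressed by
`(y(n−1)+0.5)/n`), negative binomial with log link for overdispersed
counts, and Gamma with log link for strictly positive biomass.

Sampling uses 3 chains of 5000 iterations with 2500 warmup and thinning 3.
The posterior kernel is authored in the package: adaptive random-walk
Metropolis whose covariance is tuned in a two-stage pilot run (adapt, then
refit the proposal moments from a cleaner stationary stretch) and then
frozen, so all chains run the identical kernel, plus three structure-aware
moves — independence proposals from a Gaussian fitted in *centred*
coordinates (where the posterior is closest to Gaussian), an
ancillarity–sufficiency interweaving update that slice-samples the site
standard deviation with the centred effects held fixed (eliminating the
funnel autocorrelation between the scale and the non-centred effects), a
σ-scaled translation move along the weakly identified direction
`beta + σ·mean(u)`, and a univariate slice update of the dispersion. Random
effects are non-centred, which keeps the joint posterior bounded as the
site scale approaches zero.

Priors are weakly informative and documented: zero-centred normals with
scale 5 on link-scale coefficients, half-normal(0, 1) on the site standard
deviation, and a wide lognormal on the family's auxiliary scale. All are
overridable (`prior_scale`). Every fit records its seed, chains, draw
counts, split-Rhat and effective sample size, and *fails loudly* when any
parameter's split-Rhat exceeds 1.01. Because split-Rhat estimated from a
finite effective sample carries Monte-Carlo noise of roughly ±0.01, a fit
retries up to three times with derived seeds before raising the diagnostic
error — the threshold itself is never relaxed.

Inference follows the highest-posterior-density convention: the 95% HPDI is
the shortest contiguous interval containing 95% of the sorted draws
(checked in tests against an exhaustive window search), and a pairwise
habitat contrast is flagged as an effect only when its HPDI excludes zero.

## Covariate selection and the fish models

The five complexity metrics are screened for collinearity with Pearson
|r| > 0.7; connected components of the resulting graph form collinear
blocks, and each block is collapsed to its first principal component
(columns standardised, sign fixed so the rugosity loading is positive).
Habitat exposure (tidal accessibility) is excluded from the final fish
models: censuses are taken when all habitats are accessible, and the metric
is collinear with grazing area.

Model selection uses *exact* leave-one-out cross-validation — every
observation held out in turn and the model refitted — which is feasible
because the modelling unit is the site × habitat mean (n = 15). By default
each refit's predictive density is computed from draws of the refit's
Laplace approximation rather than a full MCMC run; at this sample size the
two agree closely and the Laplace path keeps an eight-candidate all-subset
scan to a few seconds (`method = "mcmc"` runs the full sampler per refit).
Ties rank toward fewer covariates. Final fish models are Gamma log-link
hierarchical fits; covariates are standardised internally and slopes
reported on the raw covariate scale together with the posterior probability
of a positive slope and a predicted curve with its HPDI band.

## Multivariate tests

Assemblage matrices (abundance split into small/large individuals; biomass
pooled) are compared through zero-adjusted Bray–Curtis dissimilarity: a
constant dummy "species" of abundance 1 — the smallest observable
abundance, the conventional choice, configurable — is appended so that
depauperate samples have bounded, defined dissimilarities. The
dissimilarity itself is delegated to `vegan::vegdist`. The distance-based
linear model Gower-centres the squared dissimilarities,
`G = −½·J·(D∘D)·J`, and forms the marginal pseudo-F
`[tr(HGH)/1] / [tr((I−H)G(I−H))/(n−2)]` for the hat matrix of
`[1, covariate]`. Inference is by unrestricted permutation of observation
labels (the design has no stratification requiring otherwise), with the
observed statistic included: `p = (count + 1)/(n_perm + 1)`, so p is never
zero. On univariate Euclidean data the pseudo-F reproduces the classical
regression F statistic to 1e-8, which the tests exploit as an oracle, and
the implementation is cross-checked against `vegan::dbrda`. Sequential
tests and ordination plots are out of scope.

## The synthetic reef

`generate_study()` emulates the survey design: 3 sites × 5 habitats × 2
reconstruction locations × 5 transects of 5 m at 5 mm resolution, one year
of tides, nine depth soundings per unit near high tide, and three replicate
fish censuses per unit. Habitat archetypes encode the field gradient:
roughness amplitude and refuge rates peak on the slope and crest, the turf
cover probability peaks on the outer-flat (0.573, against 0.545 slope,
0.515 crest, 0.385 inner-flat, 0.30 on the macroalgae-dominated mid-flat),
and benthos levels shallow shoreward. Those cover probabilities follow the
published per-habitat grazing-area pattern for an inner-shelf fringing
reef; the roughness amplitudes and refuge rates are calibration choices
made once to reproduce the qualitative complexity ordering, not measured
values.

Terrain is midpoint displacement with per-level amplitude decay `2^(−1.3)`
and total displacement standard deviation equal to the archetype's
roughness amplitude. The decay exponent (> 1) makes local slopes soften at
fine scales: the terrain is rough at the decimetre-to-metre scales that
drive rugosity while free of near-vertical sampling artefacts at the
millimetre grid, so planted refuges — not noise — control refuge counts.
Rugosity changes by well under 2% when the sampling resolution is halved.
Crevices are carved with a flat floor a fixed depth below the lower rim and
1 cm tapered walls, which guarantees a rule-conforming notch admits the
10 cm disc regardless of the underlying terrain gradient; overhangs are
near-vertical steps spread over two samples. Fish counts are negative
binomial on a log link, `mean = exp(β0 + β1·grazing fraction)` with
β0 = 3.25, β1 = 3 and dispersion k = 5 — a gradient strong enough that the
outer-flat holds the densest assemblage, matching the field pattern — and
are allocated to a six-species pool dominated by a parrotfish, with
per-species size distributions and the two belt widths applied at
generation time. Tides are a two-constituent harmonic (12.42 h and 12 h)
whose interference produces a spring–neap cycle; real constituent data are
deliberately not required.

What passing tests show: every metric matches its geometric closed form;
planted refuges are recovered (≥ 95%, ≤ 5% spurious over 100 profiles);
the among-habitat models recover planted means, ratios and null cases; and
over 20 replicate studies the leave-one-out selection picks a
grazing-containing model whose slope HPDI excludes zero in ≥ 85% of runs
when β1 = 3, while excluding zero in ≤ 15% when β1 = 0. What they do not
show: performance on real photogrammetry, whose terrain has undercuts,
holes and non-stationary roughness; robustness to mis-segmentation of the
benthos; or transferability of the archetype calibration to other reefs.
Problem sizes in the replicated experiments (full default design per study;
60-day tide series for the recovery runs) were chosen to exercise the
complete design at each replicate.

## Degenerate inputs and edge rules

Profiles require ≥ 2 strictly increasing finite samples. Observers beyond
terrain, empty contour ranges, segmentations outside the extent, zero
transect areas, non-positive Gamma responses, constant covariates and
missing units raise immediate, named errors. Proportions are shifted off
the boundary before beta fits; an exact 1 after the offset is compressed
rather than rejected. All generators accept a seed, restore the caller's
RNG state, and derive per-transect sub-seeds below 2^31.
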