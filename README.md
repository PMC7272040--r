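# reefscape

Structural complexity shapes where reef fishes live, yet its different
facets — topographic roughness, coral cover, refuge availability, a feeding
fish's field of view — are rarely separated from the availability of the
nutritional resource those fishes actually graze. `reefscape` implements a
complete analysis pipeline for this question, aimed at reef ecologists
working with elevation cross-sections extracted from photogrammetric
reconstructions (or any transect profiler) together with timed-swim censuses
of roving herbivorous fishes (parrotfishes, surgeonfishes, rabbitfishes).

The pipeline has four layers:

1. **Transect metrics** from an elevation cross-section `z(x)` and its
   benthic segmentation:
   - rugosity index `RI = L_chain / D_chain` (contoured over planar length),
   - verticality `A(x) = |f(b) − f(a)| / 10 cm`, averaged over 10 cm
     intervals,
   - hard-coral cover and grazing surface area (epilithic algal matrix) as
     contour-length fractions,
   - refuge density: crevices 10–20 cm wide and ≥ 10 cm deep that admit a
     10 cm disc, plus near-vertical surfaces > 10 cm high,
   - feeding field of view: per observer (eye 2.5 cm above the benthos,
     every 1 m from 0.5 m, sight length 2.5 m) the visible fraction
     `(90° − θ)/90°` of the upward quadrant, where θ is the largest angle
     subtended by terrain.
2. **Tides**: Rule-of-Twelfths interpolation between tide extremes,
   tide-corrected depths, and the percentage of the year each habitat holds
   at least 30 cm of water (the depth needed by roving herbivores).
3. **Fish surveys**: belt-transect standardisation (5 m belt for fishes
   > 10 cm TL, 1 m belt below), size-class midpoints through length–weight
   allometry `W = a·L^b`, densities per 250 m², replicate censuses averaged.
4. **Models**: Bayesian hierarchical among-habitat comparisons
   (`metric ~ habitat + (1 | site)`, Gaussian / beta / negative-binomial /
   Gamma families, 3 chains × 5000 iterations, 95% HPDIs, pairwise
   contrasts), a covariate-selection workflow (Pearson |r| > 0.7 screen →
   PC1 composite → exact leave-one-out selection), Gamma log-link
   fish-distribution models, and zero-adjusted Bray–Curtis distance-based
   linear models with permutation pseudo-F tests.

A seeded synthetic-reef generator (`generate_study()`) emulates the full
survey design — 3 sites × 5 habitats (slope, crest, outer-, mid-,
inner-flat) × 2 reconstructions × 5 transects of 5 m — with known ground
truth for every stage, so the whole pipeline is testable end to end without
any field data.

## Worked example

```r
library(reefscape)

study   <- generate_study(seed = 1)     # 150 transects, 15 site x habitat units
metrics <- study_metrics(study)
units   <- aggregate_units(metrics, study$depths, study$tides)

dplyr::summarise(dplyr::group_by(metrics, habitat),
                 rugosity = mean(rugosity), grazing = mean(grazing_area))
#>   habitat    rugosity grazing
#> 1 crest          1.69   0.527
#> 2 inner_flat     1.03   0.374
#> 3 mid_flat       1.07   0.321
#> 4 outer_flat     1.14   0.597
#> 5 slope          1.64   0.568
```

Complexity peaks on the slope and crest and collapses shoreward, while the
grazing surface area peaks on the outer-flat — the divergence that drives
the analysis. Relating fish abundance to the habitat covariates:

```r
units$complexity_pc1 <- pc1_composite(
  units, c("rugosity", "verticality", "coral_cover", "refuge_count",
           "fov_visible"), anchor = "rugosity")$scores
asm <- build_assemblage(study$fish_surveys, study$lw_params, covariates = units)
dat <- dplyr::left_join(asm$units, asm$covariates, by = c("site", "habitat"))

fit <- fit_fish_model(dat, "abundance", "grazing_area", seed = 5)
tidy(fit)
#>   term         mean     hpdi_lower hpdi_upper ... p_positive
#> 1 (Intercept)  101.6    47.8       153.4           1
#> 2 grazing_area   3.21    2.44        4.11          1
```

The grazing-area slope (on the log scale, per unit grazing fraction) is
recovered close to the generator's planted value of 3, with posterior
probability ~1 of being positive. `plot_fish_relationship(fit, dat)` draws
the fitted curve with its 95% HPDI band; `loo_select()` ranks candidate
covariate sets by exact leave-one-out predictive density;
`run_marginal_suite(asm)` gives the multivariate pseudo-F tests.

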