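# berryflux

Oxygen budgets of millimetre-sized photosynthetic microbial aggregates
("green berries", cyanobacterial colonies, marine snow) from Clark-type
microsensor data.

Dense aggregates of phototrophs and heterotrophs exchange O2 with the
surrounding water by molecular diffusion alone. The O2 field in and around
an aggregate therefore encodes its whole metabolic budget: supersaturated
cores in the light, core anoxia in darkness, and an external concentration
gradient whose shape gives the total exchange rate. `berryflux` is for
microbial ecophysiologists who profile such aggregates with O2 microsensors
and want the full chain from raw depth profiles and light–dark recordings to
a per-aggregate rate table.

## The model and the estimators

The aggregate is a sphere of radius *R* (ESD/2) with uniform volumetric
reaction rate *Q* (production positive) and internal diffusivity *θD_w*, in
water with diffusivity *D_w* and ambient concentration *C∞*. At steady state

    C(r) = C_R + Q (R² − r²) / (6 θ D_w)            r ≤ R
    C(r) = C∞ + Q_tot / (4π D_w r)                  r ≥ R   (stagnant medium)

with `Q_tot = Q·V` the whole-aggregate rate; a finite diffusive boundary
layer δ is available. Setting C(0) = 0 gives the critical respiration
(diffusion-limitation) threshold

    Q_crit = C∞ / [R² (1/(3 D_w) + 1/(6 θ D_w))].

On top of this forward model the package provides:

- `whole_aggregate_flux()` — total O2 exchange from a depth microprofile by
  a least-squares fit of the external 1/r field (plus a planar Fick
  alternative), with standard error and CI;
- `gross_photosynthesis()`, `light_dark_shift_rate()` — gross production by
  the net + dark-respiration sum and by the initial O2 decline after
  darkening;
- `carbon_fixation()`, `resp_to_gross_ratio()`, `build_rate_table()` — the
  assembled per-aggregate and volumetric budget;
- `simulate_transient()`, `time_to_anoxia()` — conservative finite-volume
  solver for light–dark shift dynamics (deSolve under the hood);
- `acetylene_reduction_rate()`, `cn_molar_ratio()` — nitrogenase-assay and
  elemental C:N arithmetic with the dark-hours photoperiod convention;
- `berry_scenario()`, `generate_profile()`, `generate_ld_trace()`,
  `generate_incubation_table()` — seeded synthetic microsensor data from the
  forward models, so every estimator is testable without raw recordings.

## Worked example

Generate noise-free synthetic profiles under the standard scenario
(ESD 1.7 mm, volume 2.8 mm³, dark respiration 6.8 µmol cm⁻³ h⁻¹, net
production 4.8 / 11 µmol cm⁻³ h⁻¹ at 170 / 320 µE m⁻² s⁻¹) and recover the
budget:

```r
library(berryflux)
spec <- berry_scenario(noise_sd = 0)
dark <- generate_profile(spec, light_ue = 0)
lit  <- list(generate_profile(spec, 170), generate_profile(spec, 320))
build_rate_table(dark, lit, spec$geometry, spec$medium, spec$model)
#> Aggregate O2 rate table (per-aggregate nmol/h, volumetric umol/cm3/h):
#>  light uE dark resp vol dark net phot vol net gross phot vol gross L-D shift C fix ng/h
#>         0        19      6.7       NA      NA         NA        NA        NA         NA
#>       170        NA       NA       13     4.8         32      11.5        NA        323
#>       320        NA       NA       31    11.0         50      17.7        NA        497
```

Dark respiration of 19 nmol h⁻¹ recovered from the profile, net
photosynthesis 13 and 31 nmol h⁻¹, gross = net + respiration, and carbon
fixation = gross/PQ × 12.011 with PQ = 1.2. The diffusion-limitation
threshold for this geometry,

```r
critical_respiration(aggregate_geometry(1.7), medium_properties(24, 35))
#> [1] 4.479568
```

(µmol cm⁻³ h⁻¹), is well below the observed 6.8, so darkness drives the core
anoxic — in minutes:

```r
tr <- simulate_transient(spec$geometry, spec$medium, spec$model,
                         light_schedule(0, 600, -6.8), initial = 520)
time_to_anoxia(tr)
#> [1] 6.243773
```

i.e. a core starting at 520 µmol L⁻¹ falls below 1 µmol L⁻¹ about 6 minutes
after the light goes off.

The methods vignette (`vignettes/oxygen-budget-methods.Rmd`) documents the
model assumptions, parameter defaults, solver numerics, and what the
synthetic generator does and does not emulate.

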