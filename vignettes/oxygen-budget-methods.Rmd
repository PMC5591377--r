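---
title: "Oxygen budgets of photosynthetic aggregates: models, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen budgets of photosynthetic aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berryflux)
```

## The system and the model

Millimetre-sized aggregates of unicellular cyanobacteria, diatoms and
heterotrophic bacteria — "green berries" and comparable marine snow
particles — run intense, tightly coupled photosynthesis and respiration in a
gel-like matrix a few hundred micrometres to millimetres across. Exchange
with the surrounding water is purely diffusive at this scale, so the O2
field inside and around an aggregate carries the whole budget: supersaturated
cores under illumination, anoxic cores in darkness, and a boundary-layer
gradient whose shape encodes the total exchange rate.

`berryflux` treats the aggregate as a sphere of radius $R$ (half the
equivalent spherical diameter, ESD) with a *uniform* volumetric reaction rate
$Q$ (net O2 production positive, respiration negative) in a diffusive
medium. At steady state,

$$C(r) = C_R + \frac{Q}{6\,\theta D_w}(R^2 - r^2), \qquad r \le R,$$

inside the aggregate, where $\theta$ is the ratio of apparent diffusivity in
the matrix to the free-water diffusion coefficient $D_w$, and outside

$$C(r) = C_\infty + \frac{Q_{tot}}{4\pi D_w}\left(\frac{1}{r} -
\frac{1}{R+\delta}\right), \qquad R \le r \le R+\delta,$$

with $Q_{tot} = Q\,V$ the whole-aggregate rate and $\delta$ the diffusive
boundary layer (DBL) thickness; $\delta \to \infty$ gives the stagnant
infinite-medium form $C = C_\infty + Q_{tot}/(4\pi D_w r)$, and
$\delta \to 0$ clamps the surface to the ambient concentration. Setting the
centre concentration to zero gives the diffusion-limitation threshold
implemented by `critical_respiration()`:

$$Q_{crit} = \frac{C_\infty}{R^2\!\left(\frac{1}{3 D_w} +
\frac{1}{6\,\theta D_w}\right)} \quad (\text{stagnant case});$$

respiration above $Q_{crit}$ makes the core anoxic no matter how oxic the
bulk water is. For an ESD of 1.7 mm at 24 °C this threshold sits near
5 µmol cm⁻³ h⁻¹ (see *Parameters* for the spread induced by the ambient
concentration choice), well below the dark respiration such aggregates
actually sustain — which is why they flip to core anoxia within minutes of
darkening.

## Parameters that matter

| parameter | meaning | unit | default | source of the default |
|---|---|---|---|---|
| `d_w` | O2 diffusion in water | cm² s⁻¹ | 2.175e-5 at 24 °C, 2.3535e-5 at 27 °C, linear in between | printed anchors for 3.5% saline water |
| `theta` | apparent diffusivity ratio in the matrix | — | 0.95 | standard value for gel-like aggregates |
| `c_sat` | ambient/bulk O2 | µmol L⁻¹ | Garcia–Gordon air saturation at (T, S) | see below |
| `pq` | photosynthetic quotient | mol O2 / mol C | 1.2 | standard marine value |
| `dbl_um` | boundary-layer thickness | µm | `Inf` (stagnant) | see below |
| `anoxia_umol_l` | "full anoxia" threshold | µmol L⁻¹ | 1 | sensor noise floor |

**Ambient concentration and the salinity ambiguity.** The source
measurements were calibrated in 3.5% NaCl but the pool water was reported as
"3.5 psu"; the two readings of the ambient O2 differ by about 20%
(≈210 vs ≈258 µmol L⁻¹ at 24 °C). The package does not resolve the
ambiguity: `medium_properties(24, 35)` and `medium_properties(24, 3.5)` give
both candidates and `c_sat` can be overridden with a measured value. The
critical-respiration threshold computed under the two candidates brackets
the commonly quoted 5.0 µmol cm⁻³ h⁻¹ (4.5 from the seawater reading, 5.5
from the brackish one), which is also the honest statement of the model's
precision here. Air saturation itself uses the Garcia & Gordon (1992) refit
of the Benson–Krause data (µmol kg⁻¹ coefficients, reported per litre under
a freshwater-density approximation of < 3%).

**Stagnant default.** The stagnant infinite medium is the default external
model even though profiling rigs usually stir the water slightly: the
1/r far field is what whole-profile flux estimation fits, and a finite
`dbl_um` is available whenever the boundary layer was actually measured.

**Geometry and the working volume.** `aggregate_geometry()` derives ESD as
the geometric mean of three principal diameters and defaults the volume to
the ESD sphere (π/6·ESD³). The volume is nevertheless independently
settable, because published budgets sometimes pair an ESD with a working
volume measured on a different individual (1.7 mm ESD implies 2.57 mm³, yet
per-aggregate/volumetric rate pairs may be quoted for 2.8 mm³). All
per-aggregate totals — the external 1/r field, the transient source, the
rate table — use `volume_mm3`, so quoted budgets reproduce exactly; when the
volume differs from the ESD sphere, the interior/exterior flux match at the
surface is approximate (exact for the default), and local volumetric rates
inside the modelled sphere are rescaled by `V / V_sphere` (≈ 1.09 for
2.8/2.57) to keep the totals right.

## Estimators

**Whole-aggregate flux** (`whole_aggregate_flux()`). The default radial
estimator maps depths above the aggregate surface to radial distance
(assuming the profile passes through the centre), fits $C = C_\infty + k/r$
to the external points by least squares, and reports $4\pi D_w k$ with a
standard error and confidence interval from the fit. The window default —
points at least 50 µm off the surface and within one ESD — excludes
sensor-contact artefacts near the interface and far-field points that carry
no gradient information. A planar Fick alternative
($J = -D_w\,dC/dz$ times the sphere surface) is provided for comparison
with flat-geometry workflows; on a spherical source it reads low, because
the planar extrapolation ignores radial spreading.

**Gross photosynthesis.** Two routes, mirroring field practice:
net efflux in the light plus dark respiration magnitude
(`gross_photosynthesis()`, assuming light respiration equals dark
respiration), and the light–dark shift (`light_dark_shift_rate()`): the
initial O2 decline right after darkening equals the local gross production,
because respiration continues while production stops and the diffusive field
has not yet relaxed. The default fit window of 2–12 s after darkening skips
the first two seconds (sensor response and switching transients); windows
much beyond ~15 s read increasingly low as diffusion resupplies the point —
the package reproduces that bias on synthetic traces, and it is one reason
centre-point shift rates sit below profile-derived volumetric gross rates.

**Carbon and nitrogen arithmetic.** `carbon_fixation()` divides gross O2 by
the photosynthetic quotient; `acetylene_reduction_rate()` normalizes GC
ethylene totals by dry mass and by the hours fixation is assumed active —
by default only the dark hours of the photoperiod, the usual convention for
unicellular cyanobacteria, with partial final cycles contributing completed
dark periods plus any partial overlap (spans are taken to start at light
onset). `cn_molar_ratio()` is the mass-to-molar conversion.

## Transient solver numerics

`simulate_transient()` integrates the spherically symmetric
diffusion-reaction equation with conservative finite volumes: uniform shells
inside the aggregate (60 by default), power-stretched shells outside (90) up
to `R + l_cm` (ten radii for a stagnant far field, or the DBL thickness),
harmonic-mean interface diffusivities, a zero-flux symmetry cell at the
origin, and a far-field Dirichlet (or optionally reflecting) outer boundary.
Time integration is `deSolve::ode.1D` (lsoda) with rtol 1e-6 and atol
1e-3 µmol L⁻¹. Two choices deserve a note:

- *No consumption of absent O2*: a consuming source ramps linearly to zero
  below 0.5 µmol L⁻¹ (`src_eps`). The hard cutoff at exactly zero makes the
  stiff integrator chatter at the anoxic front; the ramp is the standard
  first-order-kinetics regularization and sits below the 1 µmol L⁻¹ anoxia
  threshold, so crossing times are unaffected at the reported precision.
  Residual negative excursions are clipped in the output.
- *Grid convergence*: doubling both cell counts moves the time-to-anoxia of
  the standard dark-shift run by < 0.1%, and the long-time solution matches
  the analytic steady state to better than 0.1 µmol L⁻¹ on the default grid
  — both are asserted in the test suite.

For the canonical darkening experiment the initial condition is idealized as
a uniform supersaturated core (e.g. 520 µmol L⁻¹) inside and ambient water
outside — stated explicitly because the real pre-darkening field is the
lighted steady profile; the idealization changes the anoxia time by well
under a minute.

## What the synthetic generator does and does not emulate

`generate_profile()`, `generate_ld_trace()` and
`generate_incubation_table()` draw from the forward models with additive
i.i.d. Gaussian sensor noise (default σ = 2 µmol L⁻¹), on a 50 µm depth grid
and 1 Hz trace sampling, all randomness fixed by the scenario seed
(byte-identical files on re-run). `berry_scenario()` encodes the study
conditions: ESD 1.7 mm, working volume 2.8 mm³, 24 °C, θ = 0.95, PQ = 1.2,
dark respiration 6.8 µmol cm⁻³ h⁻¹, net production 4.8 and 11 µmol cm⁻³ h⁻¹
at 170 and 320 µE m⁻² s⁻¹.

The generator does **not** emulate: depth-dependent light attenuation (the
uniform-source model deliberately over-predicts measured core
concentrations under strong light), stirring artefacts, sensor drift or
calibration error, response-time convolution, lateral offsets of the
profiling line from the centre, or aggregate-to-aggregate biological
variability. Estimator tests passing on synthetic data therefore demonstrate
internal consistency (each estimator inverts the forward model it assumes)
and noise robustness — not that the uniform-reaction sphere is an adequate
description of any particular real aggregate.

## Worked example

```{r example}
spec <- berry_scenario(noise_sd = 0)
dark <- generate_profile(spec, light_ue = 0)
lit <- list(generate_profile(spec, 170), generate_profile(spec, 320))
build_rate_table(dark, lit, spec$geometry, spec$medium, spec$model)

critical_respiration(aggregate_geometry(1.7), medium_properties(24, 35))

tr <- simulate_transient(spec$geometry, spec$medium, spec$model,
                         light_schedule(0, 600, -6.8), initial = 520)
time_to_anoxia(tr)  # minutes
```

## Known limitations

- The uniform volumetric source is the strongest assumption: photosynthesis
  tracks the internal light field and respiration tracks biomass, neither of
  which is uniform. Profile-derived *totals* are insensitive to the internal
  distribution (they only read the external far field), but core
  concentrations and point shift rates are not.
- The 1/r estimator assumes the measured line passes through the aggregate
  centre and that the external field is at steady state.
- The dark-hours convention for acetylene reduction is an assumption about
  the organism's diel physiology, not a measurement; `active_phase`
  exposes it.
- Concentrations are treated as volumetric (µmol L⁻¹) throughout; at
  salinity 35 the kg/L distinction in the solubility fit is a ~2.5% effect,
  absorbed by overriding `c_sat` where it matters.
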