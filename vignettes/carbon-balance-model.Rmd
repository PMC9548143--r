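---
title: "A desk-scale process model of China's terrestrial carbon balance, 1900-2000"
author: "ChinaCarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale process model of China's terrestrial carbon balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models, and what it deliberately does not

ChinaCarbon is a transparent surrogate for the regional application of a
process-based terrestrial biogeochemistry model: monthly gridded carbon
fluxes and pools for China over 1900-2000, the equilibrium / spin-up /
transient protocol, and a four-member factorial experiment attributing
changes in the national carbon sink to CO2, climate and land use. The flux
identities, state structure, protocol and diagnostics are those of the
full-scale models; the flux *formulations* are intentionally simple,
multiplicative and fully documented here, so every number the pipeline
produces can be traced and unit-tested. Nitrogen cycling, ozone, nitrogen
deposition, fire, phenology sub-models, multi-layer soil physics and
wood-product pools are out of scope. Consequently the package's outputs are
not calibrated estimates of China's historical carbon budget; they are the
behaviour of a well-specified model under well-specified synthetic forcing.

## The carbon core

For each cell, each of six cover cohorts (forest, shrubland, grassland,
wetland, cropland, bare) carries a vegetation pool `Cv` and soil pool `Cs`
(g C m^-2 of cohort area). Monthly, with `T` air temperature (degC),
`T_s` 20 cm soil temperature, `W` water-filled pore space (percent):

- **GPP** `= c_max * f_T * f_CO2 * f_L * f_W`, where
  `f_T = ((T - t_min)(t_max - T)) / ((T - t_min)(t_max - T) - (T - t_opt)^2)`
  clamped to [0, 1] and zero outside `(t_min, t_max)`;
  `f_CO2 = (C/(k_c + C)) / (340/(k_c + 340))` clamped to [0, 1], so 340 ppm
  is the reference and fertilization saturates there;
  `f_L = 1 - cloud_ext * cloud`; and `f_W` ramps 0 to 1 over WFPS 0-60%
  then falls linearly to 0.6 at saturation (anaerobic stress).
- **RA** `= rm + r_g * max(GPP - rm, 0)` with
  `rm = r_m * Cv * q10_veg^((T-10)/10)`.
- **RH** `= k_d * Cs * q10_soil^((T_s-10)/10) * f_W`, the same moisture
  ramp as GPP: one fewer free function, and water genuinely co-limits
  plants and microbes in this region.
- **Pools**: `litter = l_f * Cv`; `Cv += NPP - litter`;
  `Cs += litter - RH`. Respiration terms are capped by pool availability
  (`RA <= GPP + Cv - litter`, `RH <= Cs`), which is the flux adjustment
  that keeps pools non-negative while `NPP = GPP - RA`, `NEP = NPP - RH`
  and `dCv + dCs = NEP` hold *exactly* at every step — the conservation
  tests exploit this to 1e-6 relative over a century.

### Parameters

`defaultBiomeParams()` is the single parameter table (YAML-overridable via
`readBiomeParams()`). The maximum monthly GPP values
(forest 150, shrubland 60, grassland 70, wetland 90, cropland 110, bare 5
g C m^-2 month^-1), `k_c = 400` ppm and `q10_soil = 2.0` are fixed design
values. The remaining entries are this package's calibration, chosen once
so that the default scenario reproduces the qualitative historical
narrative and then frozen:

- `q10_veg = 1.2`: plant maintenance respiration acclimates; with a
  stronger Q10 the late-century warming penalty on NPP overwhelms CO2
  fertilization, which contradicts the behaviour the model is meant to
  exhibit (a growing sink with a lately-negative climate *contribution*,
  not a collapsing sink).
- Thermal optima `t_opt` of 25/22/18/22/25/15 degC: the productive
  southeastern biomes are subtropical, so warming should be beneficial or
  neutral over most of the domain.
- `cloud_ext = 0.8`: strong enough that the observed slight clearing trend
  contributes measurably to late-century productivity, and it scales
  national NPP to the ~3 Pg C yr^-1 range.
- `r_m` ~0.0035-0.005 month^-1 for natural types but 0.009 for cropland:
  cropland's higher turnover and respiration make its equilibrium NPP
  fall below forest's, so conversion of forest to cropland lowers local
  NPP — without this, young croplands (with near-zero maintenance load)
  would out-produce the forest they replace.
- Litterfall `l_f` (0.005-0.03 month^-1) and base decomposition `k_d`
  (0.0015-0.003 month^-1) set vegetation residence times of a few years
  (grassland, cropland) to ~17 years (forest) and soil residence of
  decades, yielding a national soil pool of order 10^2 Pg C.

## Soil physics

Soil temperature at 20 cm follows first-order relaxation
`T_s' = T_s + alpha (T - T_s)` with `alpha = 0.6` month^-1: it attenuates
the annual cycle with gain
`alpha / sqrt(alpha^2 + 2(1-alpha)(1-cos w))` (tested against this closed
form to 2%) while passing long-term trends through — an adequate stand-in
for heat diffusion at this depth, though it cannot reproduce the *trend*
attenuation a diffusive deep soil would show.

Water is a single bucket of texture-derived capacity
`150(1 - clay) + 50` mm. Monthly: Thornthwaite PET from temperature and
day length (`16 (10T/I)^a`, zero at or below freezing, strictly increasing
above); AET ramps with storage, saturating at half capacity; overflow above
capacity leaves as runoff; the balance closes to machine precision (AET is
additionally capped at `water + precip`, a small tightening of the ramp
needed for exact closure when PET exceeds half the capacity). WFPS =
100·storage/capacity drives both GPP and RH.

Known degeneracy: in a few very wet cells the AET ramp's switching at half
capacity sustains a quasi-periodic storage oscillation that never settles,
so annual NEP hovers around ~10 g C m^-2 yr^-1 indefinitely. These cells
(4 of 558 on the default grid) are honestly flagged non-converged by
`runEquilibrium`; their contribution is far inside the national
equilibrium bound. No snowpack or freeze lock-up is modelled, a fidelity
loss for northeastern winters.

## The simulation protocol

`runEquilibrium` iterates the mean annual cycle (century-mean climatology;
CO2 at the 1900-2000 mean) until |annual NEP| < 0.1 g C m^-2 yr^-1 for
five consecutive years per cell, up to 3000 years; non-convergence is
flagged, never silent. Because RH is linear in `Cs`, the accelerator
periodically rescales the soil pool by its litter/RH ratio (and nudges
`Cv` toward the NPP/litterfall balance) during the first 1000 years; the
final approach is always pure relaxation, so the converged state is a
genuine fixed point — verified against the closed-form steady state for
constant forcing to 1%.

`runSpinup` then cycles the 1900-1949 climate block three times (150
years) with CO2 and land cover at 1900, imprinting interannual variability
on the initial state. `runTransient` honors the experiment modes: S2 holds
CO2 at the first-year value; S3 replays the 1900-1919 *mean monthly cycle*
(12 values per variable per cell — the natural reading of a "1900-1919
average" climate); S4 freezes cover fractions. Factor effects are
differences of decadal national NEP means, `S1 - S2` (CO2), `S1 - S3`
(climate), `S1 - S4` (land use), plus an interaction residual; the
factorial design table, not the figure caption that contradicts it, is the
authority followed for this mapping.

Land-use transitions apply each January before flux computation. Cleared
vegetation carbon splits 50/50 between immediate release (spread over the
12 months of the year) and the cropland soil pool; converted soil carbon
moves entirely; abandonment transfers cropland pools into the expanding
natural cohorts with no release, so the post-abandonment sink emerges from
regrowth dynamics rather than an instant biomass grant.

## The synthetic forcing generator

The generator is first-class, tested code; its defaults *are* the study
conditions:

- **Temperature**: latitude-graded climatology (`38 - 0.75 lat` degC) with
  a seasonal amplitude growing northward, plus a piecewise-linear warming
  of 0.3 degC over 1900-1970 and 0.9 degC over 1970-2000 — about 1 degC
  between the 1900s and 1990s decadal means, 0.30 degC/decade over
  1971-2000.
- **Precipitation**: annual totals decay exponentially from 1600 mm at the
  southeast corner toward the northwest, concentrated in summer, with
  mean-one lognormal anomalies and *no* prescribed trend.
- **Drought**: 1922-1932, precipitation times 0.6 in cells north of 33 N
  or east of 108 E — injected multiplicatively so removing it restores the
  baseline exactly.
- **Noise structure**: annual AR(1) anomalies (lag-1 rho 0.3) shared
  within the four quadrant blocks of the grid, plus block-shared monthly
  noise. White noise would never produce the decadal wet/dry spells the
  strip-anomaly diagnostics are meant to show; block sharing gives the
  spatial coherence that makes regional droughts and pluvials possible.
- **Cloudiness**: 0.65 (SE) to 0.45 (NW), declining 0.04 per century.
- **CO2**: 296 to 369 ppm along an accelerating exponential; endpoints are
  anchored exactly and increments grow monotonically.
- **Land cover**: cropland follows a national trajectory (0.07 in 1900,
  0.13 in 1980, 0.115 in 2000) laid down preferentially in the southeast;
  the non-crop remainder is split across natural types proportionally to a
  fixed reference map (the remainder-allocation rule), which grades from
  forest in the southeast to grassland and bare ground in the northwest.
- **Soil**: clay-richer southeast, sandier northwest; capacity from the
  clay pedotransfer stand-in above; elevation rising toward the west.

What the generator does **not** emulate: orography and monsoon dynamics,
spatially varying trend patterns, observational error, snow, and any
covariance between climate and land-use change. Passing tests therefore
demonstrate correct model behaviour under controlled statistical
conditions, not skill against observations.

## Numerical and design choices

- 365-day no-leap calendar, months 31/28/...; time stored as months since
  1900-01; cells ordered latitude-fastest with centers at
  `bound + (i + 0.5) resolution`. Default grid 2 degrees (18 x 31 cells)
  so a century factorial runs in about a minute; 0.5 degrees is available
  through `GridSpec`.
- Decades are the clean blocks 1900-1909 ... 1990-1999; year 2000 joins
  century-wide statistics but no decade.
- Spherical-zone cell areas; no equal-area reprojection.
- The Hu Huanyong line partition is the sign of a cross product against
  the Heihe-Tengchong segment; on-line points count as southeast.
- Spearman correlation is Pearson on average ranks with the t
  approximation for p; partial correlation residualizes rank transforms by
  least squares (residuals that vanish to rounding are reported as a zero
  partial correlation, not noise). Significance masking is two-sided 95%.
  Spatial (across-cell, century means) and temporal (across-year, national
  series) correlation tables are both provided because regional analyses
  mix the two readings.
- Archives are SummarizedExperiment objects (assays = cell x month flux
  and soil-state matrices) written as directories of full-precision CSV
  matrices plus a JSON manifest; `%.17g` formatting makes write/read
  round-trips bit-exact, and rerunning a configuration reproduces output
  files byte-for-byte.

## Problem sizes used by the test suite

The suite exercises the full century on the default 2-degree grid for the
narrative checks, a 10 x 10 grid for conservation and equilibrium
stationarity, ~30-cell grids for factorial recovery, and minute grids
(4-16 cells) for unit-level properties — sizes chosen so the entire suite
documents the model's behaviour in a few minutes on one core.

## Limitations

Beyond the scope exclusions above: CO2 fertilization saturates at 340 ppm
by construction, so late-century sink growth relies on pool lag, cloud
clearing and land abandonment; the bucket's AET ramp can oscillate in
perennially wet cells (flagged); soil-temperature trends are not
attenuated with depth; and all parameter defaults are calibration choices
of this package, asserted nowhere as measurements.
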