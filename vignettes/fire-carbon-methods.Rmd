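---
title: "Fire, burn severity and the boreal carbon balance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire, burn severity and the boreal carbon balance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealburn)
library(dplyr)
```

`borealburn` couples three pieces: a satellite burn-severity chain, a
reduced-form monthly carbon–nitrogen ecosystem kernel with fire disturbance,
and cohort-based regional bookkeeping that contrasts a fire scenario with
its no-fire counterfactual. This vignette documents the science of each
piece, the tunable parameters, the synthetic-data generator that stands in
for real inputs, and the design decisions taken where the problem was
genuinely open. Nothing here states an empirical result that the test suite
or the acceptance script does not itself compute.

## 1. The burn-severity chain

Burn severity enters as the differenced Normalized Burn Ratio. For a
two-band scene, `compute_nbr()` evaluates
$$\mathrm{NBR} = \frac{B4 - B7}{B4 + B7}\times 1000,$$
with near-infrared ($B4$) and shortwave-infrared ($B7$) reflectance;
pixels with $B4+B7=0$ are flagged missing. Only scenes acquired between
July 15 and September 15 (inclusive, compared as day-of-year) enter the
summer composite, so the post-fire signal from the forest floor is
maximal. dNBR is the pre-fire-year composite minus the post-fire-year
composite.

The raw in-perimeter mean dNBR contains scene-level variation unrelated to
the fire. `background_correct()` subtracts a background estimated from a
buffer ring 1500–1800 m outside the perimeter; when the perimeter leaves no
ring on the scene, it falls back (with a warning) to the dNBR of the same
perimeter one year before the fire. The corrected value is stored as
`raw − background`, which can be negative; negative corrected dNBR is read
as "no detected burn" and floored at zero *before* the severity mapping,
not at storage time, so the record keeps the evidence.

Fires with no usable imagery get the unweighted mean dNBR of the ten fires
closest in burned area (`gap_fill()`); with fewer than ten known fires all
are used, and ties in area difference are broken by fire id so the result
is deterministic. The brute-force equivalent (sort all fires by area
difference, take ten) is kept as a test oracle.

Severity converts to combustion through two field calibrations for
black-spruce-dominated boreal forest,
$$\mathrm{CBI} = 0.0023\,\mathrm{dNBR} + 0.5561,$$
$$\text{soil \%} = 51.42\,\mathrm{CBI} - 63.49,\qquad
  \text{canopy \%} = 14.15\,\mathrm{CBI} + 48.63.$$
CBI is clamped to its defined 0–3 scale and the percentages to [0, 100]:
both regressions leave their fitted domain at the extremes (the canopy line
exceeds 100% above CBI ≈ 3.6; the soil line is negative below
CBI ≈ 1.2347), and the clamp is the only reading under which the chain
stays physical. Two consequences are worth stating explicitly:

* the soil line crosses zero at dNBR ≈ 295.06, so organic soil barely
  combusts below roughly dNBR 300 — this drives much of the severity
  structure downstream;
* because CBI saturates at 3 (dNBR ≈ 1062.6), the severity chain is
  invertible only between the zero crossing and that saturation point.
  `soil_fraction_to_dnbr()` implements the inverse, which assigns
  severities to fires that predate the satellite record from field-observed
  organic-layer loss.

```{r severity}
soil_fraction_to_dnbr(c(0.40, 0.65))
cbi_to_fractions(dnbr_to_cbi(c(100, 300, 600)))
```

## 2. The ecosystem kernel

The simulator is a deliberately compact monthly box model of one land
cohort: vegetation carbon $C_v$, soil organic carbon $C_s$, soil organic
nitrogen $N_o$, available inorganic nitrogen $N_a$, plus foliage fraction,
moss-layer depth, a soil water bucket and a smoothed-temperature memory.
It is *not* a port of any full ecosystem model; every functional form below
is this package's own choice, selected to be the simplest structure that
reproduces the qualitative post-fire dynamics a process model and field
chronosequences show.

**Physical diagnostics.** Soil temperature is exponentially smoothed air
temperature minus an insulation offset proportional to moss depth
(`insulation` = 0.065 °C cm⁻¹, asymptotic depth 20 cm): removing the moss
layer warms the soil by ~1.3 °C, inside the 0.9–1.5 °C band reported for
boreal fire sites. Soil moisture is a single bucket (250 mm capacity):
precipitation in; evapotranspiration proportional to above-freezing air
temperature with a bare-soil evaporation floor (`et_base` = 0.95) so that
only 5% of ET scales with foliage; a baseflow drainage term (0.2 month⁻¹)
keeps the bucket off saturation so the moisture scalars stay responsive.
The ET floor is what keeps the post-fire moisture response in the
observed sub-percentage-point range while preserving its sign (burned
stands sit wetter).

**Fluxes.**
$$\mathrm{NPP} = \min\!\big(\mathrm{NPP_{max}}\, f_{fol}\, g_T\, g_W\, g_N\,
 g_{CO_2},\; \mathrm{CN_{veg}}\times \text{N supply}\big),$$
with a Gaussian temperature response ($T_{opt}=15$ °C, width 13 °C),
Michaelis–Menten moisture and available-N scalars, and a
$1+0.4\ln(\mathrm{CO_2}/280)$ fertilization term. The Liebig minimum with
the month's nitrogen supply makes plant uptake always equal NPP/CN$_v$,
which (a) conserves nitrogen exactly and (b) pins the equilibrium
available-N pool at deposition/leaching — without it the N cycle has a
quasi-neutral direction and the coupled system drifts for centuries.
Heterotrophic respiration is first-order in soil C with a Q10 of 2
(reference 5 °C) and a moisture scalar; litterfall is linear in vegetation
C; net N mineralization releases N at the soil's actual N:C ratio with a
fixed microbial immobilization share (40%). A small dissolved-organic-N
loss (0.0002 month⁻¹) balanced by deposition+fixation (0.09 g N m⁻²
month⁻¹) anchors the absolute N stock.

**Integration and mass balance.** Explicit Euler at the monthly step —
fluxes are small relative to pools at this resolution, so no sub-stepping.
The carbon identity $\Delta(C_v+C_s) = \mathrm{NPP}-R_H-\text{fire
emission}$ holds to machine precision at every step and is asserted in the
tests. A pool going negative aborts the step loudly; it means a rate
parameter is wrong, and clipping would hide it.

**Fire.** `apply_fire()` removes `canopy_frac` of vegetation C and
`soil_frac` of soil C as direct emissions. Nitrogen follows fire chemistry:
N volatilizes at lower temperature than carbon chars, so soil organic N is
removed super-proportionally (fraction $(1+0.5)\times$ `soil_frac`, capped
at 1) and leaves entirely with the smoke, while half the N in combusted
biomass returns as available N (the ash pulse). The temporary depression of
the soil N:C ratio is what produces the fire-year dip in net N
mineralization and its slow recovery as fresh litter rebuilds the ratio;
the ash pulse is what lets NPP recover faster than foliage alone would
allow. Foliage recovers linearly for 5 years (closing 30% of the canopy
gap) and then logistically (steepness 0.35 yr⁻¹, midpoint 12 yr),
continuous at the junction; moss depth relaxes exponentially with a 20-year
e-folding time.

**Calibration.** The defaults were tuned once, as a set, so that (i) the
spun-up stand sits near observed boreal black-spruce stocks (~2.2 kg C m⁻²
vegetation, ~10.1 kg C m⁻² soil; the kernel's fixed point is 2123 and
9560 g C m⁻², and `cohort_state()` defaults to that fixed point so spin-up
is stable and doubling its length changes stocks by well under 1%); and
(ii) the post-fire severity structure holds: first-year heterotrophic
respiration rises slightly for dNBR below the soil zero crossing (warmer-
and-wetter effects win when no soil burns) and falls above it (soil C loss
wins); the NEP difference between scenarios largely closes by post-fire
year 25; the soil share of direct emissions rises with severity class.
They ship as code in `ecosys_params()` and are not per-run dials.

```{r kernel}
p <- ecosys_params()
st <- cohort_state(params = p)
c(cveg = st$cveg, csoil = st$csoil)
```

## 3. Cohorts and regional accounting

Fire perimeters are overlaid on the cell grid at 1-km raster resolution
(`build_cohorts()`): every distinct (cell, fire-history) combination is one
cohort carrying its within-cell area fraction; overlapping fires from
different years yield reburn cohorts, and the never-burned remainder of
each cell is its own cohort. Rasterized overlay was chosen over exact
polygon geometry because perimeters are axis-aligned rectangles here and
the fraction error is bounded by pixel size — the tests compare against a
pixel-counting oracle. A reburn applies its severity to the current,
partially recovered state, the only choice consistent with cohort
bookkeeping.

`run_scenario()` spins each cell up for 120 years under its mean-seasonal
climatology and runs every cohort of the cell from that shared state — the
same spun-up state serves the fire and no-fire scenarios, so their
differences are attributable to fire alone. Aggregation weights cohorts by
area fraction within the cell and cells by forested area, with the unit
chain g C m⁻² × km² × 10⁻⁶ = Tg C asserted in tests. The ledger keeps
cumulative NEP (CB) and CBF = CB − cumulative direct emissions, an identity
maintained every year; `carbon_balance()` closes the accounting —
the fire-attributable storage reduction is the NEP gap plus direct
emissions.

## 4. Reports

`chronosequence()` re-indexes once-burned cohorts by years since fire and
averages scenario differences within seven dNBR classes of width 100
(<100 … ≥600). Carbon pools and fluxes are reported no-fire − fire;
soil moisture and temperature fire − no-fire. Averaging is unweighted
across cohorts to match the convention of treating each cohort as one
trajectory; an area-weighted variant sits behind `weighted = TRUE`.
`emission_partition()` tracks the soil share of the direct emission and the
direct shares of cumulative totals; classes with a zero denominator report
`NA`, never 0. `indirect_ratio()` compares cumulative total emissions
(direct + respiration since fire) between scenarios, as a multiple of the
direct emission: cumulative quantities are the only reading under which the
ratio starts at 1 when respiration is untouched and drifts with recovery,
which is why that definition was adopted. All report functions are pure
functions of run outputs.

## 5. The synthetic-data generator

`synth_config()` defines the study conditions: a grid of 50 km × 50 km
cells (an idealized equal-area stand-in for a half-degree grid, so area
weighting is exact without geodesy), years 1986–2016, sinusoidal monthly
climate with Gaussian interannual noise (boreal defaults: mean annual air
temperature −3 °C with 18 °C seasonal amplitude, ~40 mm month⁻¹
precipitation peaking in summer), linearly rising CO₂, Poisson fire counts,
log-normal fire areas, and truncated-normal per-fire dNBR (mean 272.5,
SD 120, bounds [60, 1300]) so the severity histogram peaks in the 200–400
band with an area-weighted mean near 272.5. A small fraction (0.53%) of
fires carries no dNBR to exercise gap-filling. The distributional form of
fire areas is a stand-in — only the heavy tail matters to the cohort
machinery. Every generator draws from its own stream split off the master
seed (`derive_seed()`), so adding one generator never perturbs another.

`gen_scene_pair()` embeds a prescribed dNBR into a pre/post scene pair:
a uniform background drift plus pixel noise that is re-centred within the
perimeter, within the buffer ring, and elsewhere, so the severity chain
must remove the drift and recovers the embedded value to well under one
dNBR unit. Perimeters are axis-aligned rectangles throughout — geometric
fidelity is irrelevant to the arithmetic under test.

What the generator does *not* emulate: sensor physics, cloud and smoke
contamination, orbit gaps (beyond the missing-dNBR flag), real fire-shape
complexity, spatially correlated climate, and ecozone differences in the
severity calibrations. Passing tests on synthetic data therefore
demonstrate the correctness of the computational chain and the qualitative
fire-response structure, not agreement with any particular real landscape;
continental-scale totals depend on real forcings and fire records that are
out of scope here.

## 6. Numerical choices and degenerate inputs

* Dates are compared as day-of-year; the summer window is inclusive at both
  ends.
* Gap-fill ties break by fire id; pools smaller than ten use all fires.
* Corrected dNBR may be negative in records; it is floored at zero only at
  the CBI mapping.
* The truncated normal is sampled by inverse CDF — exact, vectorized, no
  rejection loop.
* `background_correct()` with an empty ring warns and falls back to
  prior-year mode; with no prior-year grid either, it errors.
* Zero-severity fires are exact no-ops (bit-identical trajectories except
  the time-since-fire clock), which the tests assert.
* The run manifest hashes config, parameters and outputs but carries no
  wall-clock timestamp, so identical configurations reproduce identical
  manifests bit-for-bit.

## 7. Known limitations

The kernel has no permafrost hydrology, thermokarst, species succession,
multi-PFT competition, insect or harvest disturbance, or microbial
community dynamics; post-fire soil warming acts only through moss-layer
loss, so cohorts below the soil zero crossing show no temperature response
at all. Net N mineralization magnitudes are kernel-specific — only the
dip-and-recover shape is meaningful. The regional grid is equal-area by
construction; mapping onto a real half-degree grid would reintroduce
latitude-dependent cell areas. Problem sizes in the shipped tests (single
cohorts, four-cell landscapes, 120-year spin-ups) were chosen as the
smallest configurations that exercise every code path with stable
statistics.
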