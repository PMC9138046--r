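---
title: "Methods: cropland-abandonment carbon accounting with a reduced vegetation model"
author: "abandonCarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cropland-abandonment carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abandonCarbon)
```

## The problem

When a planned economy collapses, cropland can be abandoned at a scale that
measurably alters a region's carbon balance: vacated fields pass through a
grassland stage and then, where the climate allows, regrow into forest,
drawing carbon from the atmosphere into biomass and soils. Quantifying that
sink with a vegetation model requires an annual gridded cropland forcing —
and the standard global reconstructions, which are anchored to international
arable-land statistics, miss most of the abandonment because those
statistics are updated infrequently and count fallow and idle land as
arable. National sown-area records capture the true interannual dynamics but
are a *different quantity* (sown area is a subset of arable land), so they
cannot replace the gridded record directly without creating a break at the
start of the study period.

`abandonCarbon` implements the full chain: reconcile the two national
records, convert the correction into a gridded forcing, run a reduced
dynamic vegetation model under alternative land-use scenarios, and attribute
the abandonment sink by differencing.

## Calibrating the cropland series

Let `fao(i)` be the arable-land record and `ref(i)` the sown-area record of
the country carrying the abandonment signal. `optimizeCountrySeries()`
anchors the level of the first at a base year while adopting the dynamics of
the second:

    opt(i) = fao(base) + ref(i) − ref(base),        i ≥ base

so `opt(base) = fao(base)` exactly (continuity with the pre-study forcing)
and every year-to-year change equals the sown-area change. A negative result
aborts: it signals inconsistent inputs rather than real area.

The correction becomes a dimensionless annual **adjustment rate**,
`rate(i) = opt(i) / fao(i)` (`computeAdjustRate()`), which equals 1 at the
base year. Countries without a sown-area reference keep their arable-land
record (their rate is identically 1). `rescaleGridded()` multiplies every
cell of the gridded cropland-fraction field inside each study country by the
country's rate for that year. Because this is a per-country scalar multiply,
the spatial pattern — in particular the rank order of cells within a country
— is untouched whenever no clamping occurs; values pushed above 1 are clamped
and the area lost is reported (`clampReport()`). Years outside the rate
record pass through unchanged, matching the use of the unmodified
reconstruction before the study period. Per-country rates are the default;
a single region-wide rate is available (`mode = "region-wide"`) because the
aggregation level of the published rate is ambiguous — output metadata
records which mode produced a field.

## The vegetation model

The model is an independent reduced implementation honouring a published
pool topology; it makes no claim of numerical equivalence to any production
DGVM. It carries five plant functional types (broadleaf tree, needleleaf
tree, cold C3 grass, warm C4 grass, cropland) on fractional cover within
each grid cell, and per PFT five vegetation pools (leaf, fine root, coarse
root, sapwood, heartwood). Dead material enters two litter pools (metabolic
from leaf and fine root, structural from the woody pools), which feed a
single decomposer pool and then a cascade of three soil pools (fast,
intermediate, slow) — six "soil-side" pools in total. Time stepping is
explicit Euler: monthly fluxes inside an annual loop of land-use change and
vegetation dynamics.

**Photosynthesis** is Jarvis-type with co-limitation: GPP per unit PFT area
is `amax × colim(fT, fW, fC) × fL`, with a Gaussian temperature response,
Michaelis responses to soil wetness and CO2, and a light response
`fL = 1 − exp(−kext · par/par0 · (lai + lai0))` saturating in both radiation
and leaf area (LAI = leaf carbon × SLA). `colim` is the smaller root of the
Collatz quadratic `θc² − (x+y)c + xy = 0` applied pairwise left-to-right
(θ = 0.8), which responds more gradually to any single factor than a hard
minimum. The establishment floor `lai0 = 0.3` exists because the pure form
of the light response is identically zero at zero leaf area: vegetation
colonising newly abandoned (zero-biomass) area could never start growing.
The floor represents seedling/understory light capture and keeps carbon
conservation exact — no biomass is created by seeding.

**Respiration and allocation.** `Ra = resp_frac × GPP`; NPP is allocated to
the five pools by fixed fractions summing to one (grasses and crops allocate
nothing to wood). Turnover is first-order per pool. **Decomposition** scales
each donor's base rate by `Q10^((T−15)/10) × w/(w+0.3)` (Q10 = 2); each
outflow is partly respired and partly transferred down the fixed cascade;
the slow pool respires fully. These are standard first-order soil-carbon
choices; the source material prints none, so the constants live in one
parameter list (`defaultModelParams()`) and a YAML round-trip
(`readModelParams()`/`writeModelParams()`).

**Soil moisture** is a one-bucket monthly balance (capacity 150 mm,
evapotranspiration proportional to temperature-scaled demand, runoff above
capacity); its relative filling is the wetness factor for both
photosynthesis and decomposition. A full land-surface coupling is out of
scope.

**Cropland** is prescribed, never competed away, and is cultivated every
year: at the end of each year the standing crop biomass is harvested, 50%
exported from the ecosystem and 50% returned to metabolic litter. Exported
carbon accumulates in an explicit *product pool*. This bookkeeping choice
makes the conservation contract exact and testable:

    Δ(vegetation + litter + decomposer + soil + product) = ΣNPP − ΣRh

to machine precision over any interval, while reported *biosphere* totals
exclude the product pool. The land-use operator alone (`applyLandUse()`)
moves biomass only between live pools and litter, so it never changes total
carbon; emissions occur through subsequent decomposition (a configurable
burn fraction defaults to 0).

**Succession.** Abandoned cropland becomes grass (cold or warm by mean
annual temperature) in the abandonment year. On forest-suitable cells
(annual precipitation ≥ 400 mm, mean annual temperature ≥ 0 °C) abandoned
grass converts to tree cover at rate `1/tauSucc` (15 yr) once the
pure-grassland establishment lag (3 yr) has passed, so a fully grassy cell
retains `exp(−t/15)` grass after `t` years of conversion and tree cover
passes 50% of the abandoned pool about 14 years after abandonment —
inside the 12–17-year window reported by field studies of post-abandonment
succession, which with the 2–3-year grassland stage motivated both
defaults. Each cell tracks its abandoned-origin grass and tree fractions
and a succession age; when new area is abandoned the age is mixed
area-weighted with the existing cohort rather than reset wholesale, so
gradual year-by-year abandonment does not indefinitely postpone
succession. Re-cultivation reclaims land in priority order — abandoned
grass first, then other grass, bare ground, and forest only as a last
resort — reflecting that fields returning to production are the recently
abandoned ones, not cleared mature forest.

## Spin-up

`spinUp()` repeats a climatological year with a fixed cropland field. The
convergence metric is the regional net carbon balance
`NBP = NPP − Rh − export` — the actual pool drift — rather than
`NPP − Rh`, because with a persistent harvest export the latter converges
to the export flux, not to zero. Because the slow soil pool's effective
turnover is several centuries, plain integration is impractical at desk
scale; after 60 transient years (and again at 120 and 180 if needed) the
vegetation pools are jumped to `NPP × allocation × turnover` and the
soil-side pools to the closed-form steady state of the linear cascade under
the recorded litter inputs and decay climatology, then integration
continues until `|NBP|` stays below 0.1% of NPP for two consecutive years.
The two-year requirement (waived for an already-equilibrated start, which
converges immediately) exists because NBP crosses zero transiently while
vegetation still grows and initial soil pools still decay — a single small
value is not equilibrium.

## Scenarios and attribution

`runThreeScenarios()` launches three runs from one spin-up state under
identical forcing: **fixed** (cropland frozen at the divergence year, climate
and CO2 still transient, isolating the land-use signal), **default** (the
uncalibrated reconstruction) and **optimized** (the calibrated field).
Before the divergence year all scenarios are driven by the default field,
so their histories are bit-identical. `attributeSink()` differences two
runs year by year; the biosphere difference is computed as the sum of its
vegetation and soil components, so additivity holds to the last bit. The
conversion ledger (`conversionLedger()`) reports gross flows — forest and
grass standing on formerly cropped area, tracked per cell by succession
origin — rather than net area differences, which is why cropland-sourced
vegetation can exceed the net change of a cover class when re-cultivation
runs in parallel. `differenceMaps()` gives the per-cell end-state pool
differences whose regional sum equals the attribution series' final value.

## Synthetic inputs

The generator module reproduces the statistical structure the analysis
assumes, so the whole pipeline runs and is tested offline:

- `genCountryTables()`: a near-flat arable-land series per country and, for
  country 1, a sown-area series that is a strict subset of arable land and
  follows a piecewise-linear collapse–minimum–partial-recovery shape. The
  defaults mirror the printed national statistics of the post-Soviet case
  (133.71 Mha arable declining ~7.8%; sown area at 85.7% of arable at the
  baseline, losing 34.5% to a minimum 17 years in, regaining 12.6% of the
  loss), with smooth noise of 0.3 Mha.
- `genHydeLike()`: a latitudinal cropland belt modulated by a smooth random
  field, nearly static in time (per-cell interannual CV ≤ 0.05, default
  0.01), optionally scaled to national totals.
- `genClimate()`: latitudinally graded temperature with a July-peaking
  seasonal cycle, precipitation increasing northward (the dry southern
  belt falls below forest suitability, giving a steppe zone), seasonal PAR,
  centred interannual anomalies, and a linear CO2 ramp (354 ppm + 1.9
  ppm/yr).

What the synthetic world does **not** contain: real topography and soils,
spatially correlated climate extremes, management intensity, fire, nitrogen
limitation, or observational error structure. Tests passing on it therefore
demonstrate the correctness of the accounting and the qualitative regime —
they do not validate the model against real-world fluxes.

## Problem sizes and numerical choices

The shipped configuration uses a 20 × 40 cell grid over a 45–65°N,
20–100°E band, three countries, three shared-history years plus a 28-year
transient, and spin-up tolerance 0.1% of NPP — sizes chosen so a full
pipeline runs in well under a minute on a laptop while every mechanism
(abandonment, succession, re-cultivation, clamping) is exercised.
Resolution, extent and all year ranges are configuration knobs. Monthly
Euler stepping caps any pool's fractional loss at 0.95 per step (flux
limiting); all pools are non-negative by construction. The default
experiment's qualitative regime — a positive attributed sink carried mainly
by vegetation, and a soil-carbon series that first dips below and later
crosses above the fixed scenario as succession replaces harvest-export
losses with retained litterfall — is asserted as a regression against the
shipped parameter set, not claimed to be parameter-free.

## Known limitations

- The model is a structural analogue, not a calibrated emulator: regional
  pool totals and sink magnitudes are not comparable to values produced by
  full-physics DGVMs at 1/12° with observed forcing.
- Vegetation dynamics beyond abandonment succession are static (no
  bioclimatic competition among natural PFTs).
- The sown-area anchoring corrects interannual dynamics but cannot correct
  any bias in the base-year arable-land level itself.
- No re-gridding: calibration and simulation share one grid.
- Single-run attribution; no parameter-ensemble uncertainty.
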