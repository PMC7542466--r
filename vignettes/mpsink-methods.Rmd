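---
title: "The mpsink column model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mpsink column model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsink)
```

## The problem

Budget analyses of the surface ocean consistently find less microplastic
(MP, 0.1–5 mm particles) than the input estimates imply should be floating
there. One candidate explanation is a *biological pump for plastic*:
particles are captured by newly forming marine snow aggregates and ingested
by zooplankton, sink inside aggregates and faecal pellets, and are released
back to the free pool at depth when the organic carrier is remineralised.
`mpsink` implements a three-compartment Eulerian model of this
entrainment–release cycle — free MP, marine-snow-bound MP (`MP_A`), and
pellet-bound MP (`MP_Z`) — coupled to a minimal
nutrient–phytoplankton–zooplankton–detritus (NPZD) ecosystem in a vertical
water column, together with the plastic-waste emission forcing, export
efficiency diagnostics, and a Latin-hypercube parameter-screening protocol.

The package deliberately reduces the 3-D earth-system setting in which this
model family was developed to independent 1-D columns: every MP source and
sink is local in the vertical, so a column captures the mechanism while
remaining runnable in seconds. Horizontal transport, sea ice, sediments and
coupled climate are out of scope.

## Model equations

All tracers obey `dC/dt = T(C) + S(C)` with `T` the vertical transport
operator and `S` local sources minus sinks. For the three MP compartments
(units: particles m⁻³):

* free MP: `S(MP) = Emis − S(MP_A) − S(MP_Z)`, plus upward advection of a
  buoyant sub-population: a fraction `F_R` of free MP below the surface
  layer rises at `w_p` = 1.9 cm s⁻¹. Particles reaching the surface layer
  stay there; nothing leaves through the sea surface.
* marine snow: `S(MP_A) = A_upt − A_rel`, with sinking at the detrital
  speed `w_D(z)`.
* pellets: `S(MP_Z) = P_upt − P_rel`, with the same sinking law.

The exchange fluxes are

* capture by forming aggregates (Monod in MP):
  `A_upt = MP/(k_P + MP) × N_agg × F_A`, where
  `N_agg = aggregate_count(src_DET_A)` converts the marine snow production
  flux (mmol N m⁻³ d⁻¹) into newly forming aggregates assuming diatom-like
  aggregates of 8.8 µg C each and Redfield C:N = 106:16. At saturation at
  most a fraction `F_A` of new aggregates each carry one particle; this is
  the only dimensionally consistent reading of applying an aggregation
  fraction to a "maximum number of aggregates", and it makes
  `A_upt ≤ F_A × N_agg` a hard bound.
* release at the remineralisation rate: `A_rel = μ_D(T) MP_A`,
  `P_rel = μ_D(T) MP_Z` — one rate for both carriers.
* ingestion by zooplankton via a Holling type II response extended with an
  MP "prey" term. Free MP is converted to the nitrogen currency of the food
  it displaces (`mp_to_nitrogen()`): particle count × particle mass
  (236×10³ t ≡ 51.2×10¹² particles, i.e. 4.609 mg per particle) ×
  food-substitution ratio `R_F:MP` × `R_N:F`. The grazed amount `G_MP` is
  converted back to particles (`P_upt`). Ingested plastic is egested to
  `MP_Z` with 100 % efficiency — none is assimilated or metabolised — but
  it *does* occupy the shared grazing denominator, so plastic in the diet
  reduces real food intake.

`R_N:F` (mol N per g food) is not uniquely fixed by Redfield ratios alone;
we define food mass through Redfield-composition organic matter
(C₁₀₆H₂₆₃O₁₁₀N₁₆P, 222.08 g per mol N), giving
`R_N:F = 4.503 × 10⁻³ mol N g⁻¹`. It is an explicit, configurable constant
of `mp_parameters()`.

At the seafloor, MP arriving in aggregates or pellets is split by the
return fraction `F_B`: returned particles enter the bottom layer as free
MP; the remainder is permanently buried (tracked in the budget ledger).

## The ecosystem stand-in

The host biogeochemistry this model family couples to is a full
three-phytoplankton ecosystem; the MP equations, however, consume only a
narrow interface: marine snow production `src(DET_A)`, pellet production,
the remineralisation rate `μ_D(T)`, NPP, and Holling II grazing. `mpsink`
therefore implements a minimal NPZD with exactly that interface:

* three phytoplankton classes (PH, CO, DZ) with Eppley temperature scaling
  (`1.066^T`), light limitation (exponentially attenuated, layer-averaged,
  attenuation 0.03 m⁻¹ — clear subtropical water) and Monod nutrient
  limitation;
* one zooplankton class grazing on CO, PH, DZ, detritus, itself and MP with
  preferences that always sum to 1. When `psi_MP` is varied, `psi_DZ` is
  pinned at 0.1 (diazotrophs are a poor food source) and the remainder is
  split equally among the other four preferences
  (`renormalise_preferences()`);
* the zooplankton maximum growth rate is capped above 20 °C, representing
  metabolic limitation in very warm water — this is what makes cool regions
  relatively efficient exporters;
* two detritus classes: free detritus (marine snow) receives phytoplankton
  mortality plus half of the zooplankton particulate losses; the pellet
  class receives the other half (`pellet_fraction = 0.5`). We treat
  unassimilated grazing and mortality as particulate and excretion as
  dissolved. With identical sinking and remineralisation for both classes,
  the summed detritus behaves exactly like a single pool, so the split
  itself does not perturb the nitrogen cycle (this is tested);
* remineralisation `μ_D(T) = μ_D0 × q10^{T/10}` with `μ_D0 = 0.048 d⁻¹`
  and `q10 = 1.4`. The gentle exponent (≈ `exp(T/30 °C)`) follows the
  temperature scaling used in the intermediate-complexity model lineage
  this ecosystem stands in for; a steep `q10 = 2` law would give tropical
  detritus an e-folding of ~3 days, attenuating particle flux faster than
  open-ocean observations support. Both constants are configurable.

Only MP capture by *marine snow production* (not pellet production) drives
`A_upt`: marine snow is the pool formed from free detritus, and pellet-MP
contact is already represented by grazing.

## Forcing and the study conditions

Plastic waste generation starts at 2×10⁶ t yr⁻¹ in 1950 and compounds at
8.4 % yr⁻¹ (annual compounding; the forcing is piecewise-constant within a
calendar year). A fraction `F_T` enters the ocean as MP after the bulk
mass-to-particle conversion (2.17×10⁸ particles per tonne). Emission is
distributed over columns by a normalised weight vector and enters only the
surface layer. Each column represents an ocean-area share equal to its
weight (total 3.61×10¹⁴ m²), so the default per-area emission flux equals
the global-mean flux; a per-column `emission_factor` can concentrate or
dilute it (coastal vs gyre regimes). This replaces the regional
emission map of the original 3-D setting, which is not reproducible in a
column.

Temperature is prescribed: a mixed layer at the column's surface
temperature (default 50 m), an exponential thermocline (e-folding 200 m)
towards 2 °C at depth. Climate change enters as an idealised linear surface
warming trend after 2000 (default off; `warming_C_per_century`), decaying
with depth (300 m scale) — a stand-in for the coupled high-emissions
response, sufficient to exercise the warming-driven decline in export
efficiency.

The default study conditions used throughout the tests and the acceptance
analysis: the 19-layer grid (50 m surface layer, second interface at 130 m,
geometric deepening to 5000 m), a tropical column at 28 °C (and a 12 °C
mid-latitude column where contrast is needed), 30 spin-up years bringing
the ecosystem to quasi-steady state, then 1950–2020 (or –2100) with
`dt = 0.5 d`. What the column generator does *not* emulate: seasonality,
lateral advection (boundary-current accumulation hotspots), winter
deep-mixing, and the geographic co-location of emissions with coastlines —
so passing tests demonstrate the vertical mechanism and budgets, not global
distribution patterns.

## Transport numerics

* Explicit Euler, operator-split: ecosystem sources → MP sources/emission →
  sinking → seafloor exchange → rise → diffusion. Sources before transport
  keeps the per-step particle budget identity exact.
* Sinking is first-order upwind flux-form with
  `w_D(z) = 7 + 0.04 z m d⁻¹` (detritus-like, depth-increasing;
  configurable). The time step must satisfy the sinking CFL condition; the
  default grid and `dt = 0.5 d` satisfy it with a wide margin, and
  violations raise an error naming the offending layer.
* The rise speed (1641.6 m d⁻¹) would violate CFL on any reasonable grid,
  so rise transport is sub-cycled internally: the number of sub-steps is
  chosen from the buoyant sub-population's effective speed `F_R × w_p`, so
  the user-facing `dt` is unaffected.
* Vertical diffusion is conservative explicit flux-form with a background
  diffusivity of 1e-4 m² s⁻¹ and 1e-3 m² s⁻¹ within the mixed layer. The
  background value is deliberately larger than open-ocean diapycnal
  estimates: in a closed column it is the only nutrient-return pathway and
  stands in for the missing 3-D supply; with a molecular-scale value the
  euphotic zone starves and the column is unrealistically oligotrophic.
* Positivity is enforced by conservative flux limiting, not clipping: all
  of a pool's sinks are scaled down together so they cannot exceed the pool
  within `dt`, and tendencies are rebuilt from the scaled fluxes. Mass is
  therefore conserved exactly (budget residuals are at machine precision)
  and no tracer goes negative. Grazed plastic carries no nitrogen into the
  food web, so the plastic and nitrogen limiters decouple cleanly.
* Detritus reaching the seafloor is remineralised into the bottom layer's
  nutrient pool — a closed-nitrogen stand-in for sediment exchange that
  keeps the 150-year nitrogen drift at rounding level.
* A NaN/Inf appearing in any tracer marks the run "numerically unstable";
  the ensemble machinery fails such members on every plausibility
  criterion.

## Diagnostics

Export efficiencies are annual-mean ratios at the 130 m interface (the
bottom of the second layer): for MP, export flux of `MP_A` (or `MP_Z`)
divided by the *gross* uptake integrated above 130 m — gross, because the
defining phrase is "uptake rates", and because gross uptake is what the
entrainment–release cycle multiplies. For particulate organic nitrogen, the
detrital export divided by NPP (marine snow class) or grazing (pellet
class) integrated above. All ratios use the convention 0/0 → 0, which also
yields zero MP export efficiency in high-latitude columns that never
receive plastic. The reciprocal of the combined MP efficiency is reported
as `uptake_export_ratio`: particles taken up per particle exported.

`missing_fraction` is the share of the total column MP inventory below the
surface layer — the model analogue of surface plastic a neuston net would
not find, defined against the top model layer (50 m) because that is the
model's "surface-observable" stock.

Profile classification (`classify_profile()`) flags a surface/sub-surface
local minimum, a sub-surface maximum below it (the signature of release at
depth), and a power-law tail (log-log R² ≥ 0.95 on ≥ 4 points; both
thresholds configurable).

## Parameter screening

`sample_hypercube()` implements a Latin hypercube over the seven MP
parameters (`F_T` ∈ [0,1], `F_R` ∈ [0,0.1], `F_A` ∈ [0,1], `k_P` ∈
[0,1000] particles m⁻³, `F_B` ∈ [0,1], `psi_MP` ∈ [0.1,0.3], `R_F:MP` ∈
[0.5,1.5]): each range is cut into n equal-probability strata under a
truncated normal (centre mid-range, sd = range/4 — the screening protocol
specifies a "normal distribution" without parameters, so these are
documented package choices), one draw per stratum, strata permuted
independently per parameter. `k_P` is additionally split across the decades
(0–1, 1–100, 100–1000) with equal member counts, mirroring the staged
protocol. Stages: `no_bio` (F_T, F_R only), `snow_only` (+F_A, k_P, F_B),
`full` (+psi_MP, R_F:MP).

The plausibility filter applies six boolean criteria (stability, inventory
below time-integrated input, pollution-rate band around the ~4 %
ocean-entry estimate with a 10× guard, a generous marine-snow aggregation
band, an inventory agreement band, and the profile-shape flags). The
published screening states most of these only qualitatively, so the bands
are configuration values with deliberately generous defaults; we make no
claim to reproduce any particular plausible-subset count. The desk-scale
ensemble default is n = 30; 700 remains a supported value.

## Known limitations

* No size classes, polymer types, explicit biofouling, photodegradation,
  or modification of carrier sinking speeds by plastic load.
* No seasonality or lateral transport; column results should be read as
  regime exemplars (tropics, mid-latitude), not as a global mean.
* The NPZD is a stand-in with stated functional forms; its absolute
  productivity depends on the effective diffusivity, but the efficiency
  *ratios* the analysis rests on are insensitive to the productivity
  magnitude (uptake and export both scale with it).
* The warming scenario is prescribed, not coupled; it exercises the
  direction of the export-efficiency response, not its climate magnitude.
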