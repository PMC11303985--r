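---
title: "An optimal behavior model for fish in a seasonal lake food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An optimal behavior model for fish in a seasonal lake food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeOBM)
```

## The model

Most process-based aquatic ecosystem models assume consumers feed at the
maximum rate the environment allows, which makes trophic coupling rigid and
tends to destabilize simulated food webs. `lakeOBM` implements the
alternative: fish choose, each day, a position `p` on a behavioral gradient
from maximal feeding (`p = 0`) to maximal predation-risk mitigation
(`p = 1`), and the feeding pressure they exert emerges from that choice.

Three parameters set the strength of the trade-off:

* `f_PM` — predation mitigation efficiency: at `p = 1`, predation mortality
  is reduced by the fraction `f_PM`.
* `f_FC` — feeding cost of mitigation: at `p = 1`, feeding activity falls
  to `1 - f_FC`.
* `f_RF` — extra metabolic cost of the feeding process, relative to basal
  metabolism.

With feeding activity `f_feed = 1 - p f_FC`, the model is built from five
relations, all biomass-specific (rates in d⁻¹, concentrations in g m⁻³):

* feeding level (gut saturation) `F = Q / (I_max + Q)` with gut-weighted
  encounter `Q = f_feed f_veg c f_gut R`;
* assimilation `g = a f_feed f_veg c R (1 - F)`, which at `f_feed = 1` is
  exactly a Holling type II response with attack rate `c f_veg` and
  handling time `f_gut / I_max`;
* total mortality `m_tot = m_nat + (1 - p f_PM) m_pred_s`;
* total metabolism `u_tot = (1 + f_RF f_feed) u`;
* a first-order smoother on predation risk,
  `m_pred_s' = (m_pred_s + 0.25 m_pred) / 1.25`, which relaxes toward a
  constant risk geometrically with factor 0.8 per step and prevents
  prey and predator efforts from flip-flopping between days.

Fitness follows Gilliam's rule: when feeding can pay for itself
(`g_pot - u_pot >= 0` at `p = 0`), `W(p) = (g - u_tot) / m_tot`, whose
maximizer equals lifetime reproductive output in a stable environment.
When the potential net gain is negative, predation is disregarded and
`W = g - u_tot`: the fish maximizes time to starvation. This yields three
regimes:

1. **normal** — `p*` maximizes the Gilliam ratio;
2. **starvation_feed** — net gain negative but better than fasting
   (`g_pot - u_pot > -u`, equivalently `g_pot > f_RF u`): feed maximally,
   `p* = 0`;
3. **starvation_stop** — feeding cannot pay its own marginal cost
   (`g_pot - u_pot <= -u`): stop feeding, mitigate fully
   (`f_feed = 0`, `p* = 1`, `W = -u`).

The threshold between regimes 2 and 3 is the point where the two candidate
strategies have equal net energy gain (`g_pot - u_pot = -u`), so the chosen
branch's fitness is never below the alternative's by construction.

### The closed form for p*

Substituting the five relations into `dW/dp = 0` and clearing denominators
gives a quadratic in `p` (the derivation was done symbolically and is
re-checked numerically by the test suite): `A2 p^2 + A1 p + A0 = 0` with,
writing `Re = R c f_veg`, `G = f_gut Re`, `mm = m_nat + m_pred_s`,

```
K  = f_FC f_RF u mm - f_PM u m_pred_s (1 + f_RF)
M  = I_max Re a f_PM m_pred_s
A2 = G f_FC^2 (G K + M)
A1 = -2 G f_FC (G K + M + I_max K)
A0 = (G + I_max)^2 K + (G + I_max) M - I_max^2 Re a f_FC mm
```

`optimal_behavior()` evaluates the real roots in (0, 1) together with the
endpoints and returns the fitness maximizer. Because the candidate set
always contains both endpoints, clamping to `[0, 1]` is automatic, and a
missing real root simply means the optimum sits at an endpoint. If the
coefficients are non-finite (overflown inputs) the solver falls back to a
numerical maximizer and signals a condition of class
`lakeOBM_numeric_fallback`. When the fitness curve is flat to within
about 1e-12, the largest candidate `p` wins: mortality weakly decreases in
`p`, so the most cautious of equally fit behaviors is the safest
tie-break. Regime thresholds are compared with an absolute tolerance of
1e-12 on specific rates.

`m_nat` must be strictly positive: it is the Gilliam denominator at full
mitigation with perfect efficiency, and a zero value would make fitness
unbounded. Configuration validation enforces this for every fish group
that runs the optimization.

### Emergent functional response

Sweeping prey availability and re-optimizing `p` at each level yields the
consumption actually exerted (`functional_response()`). With a fully
costly trade-off (`f_FC = 1`) the curve is sigmoid — Holling type III-like
— with a hard zero below the feeding-shutdown threshold. With `f_FC < 1`
and high predation risk, mitigation is cheap enough that `p*` rises
steeply with availability and consumption *decreases* over an intermediate
range of availability before rising again once `p* = 1` is reached.
Raising ambient risk moves the whole curve down. These are properties of
the solution, not assumptions; the test suite asserts them on fine
availability grids.

## Multiple prey and feeding modes

Fish menus span up to three mutually exclusive feeding modes (pelagic,
benthic, piscivorous). Decisions are taken in two steps each day,
deliberately independent of one another:

1. **Diet and mode allocation at maximized feeding.** Within each mode the
   diet is the subset of prey maximizing total assimilation under shared
   gut saturation. Ranking prey by profitability `a_i / f_gut_i`
   (assimilated energy per unit of gut capacity; ties broken by larger
   encounter `c_i R_i`, zero-`f_gut` prey always included) and keeping the
   best prefix is exactly optimal: a prey raises total assimilation
   precisely when its profitability exceeds the current scaled intake, a
   threshold that only grows as the diet expands. The tests confirm
   equality with exhaustive subset search on random menus. Effort is then
   split across modes in proportion to the ingestion each would yield.
2. **Behavioral optimization on the aggregate.** The selected multi-prey
   menu is collapsed to a single-prey equivalent: time-weighted encounter
   `CR = sum w_m c_i R_i`, encounter-weighted mean gut factor `Q/CR` and
   assimilation efficiency `A/CR`. The single-prey solver then yields
   `p*`, and realized capture is distributed over prey in proportion to
   their encounter contribution, so per-prey assimilation sums exactly to
   the aggregate `g`.

The collapse is an approximation — a diet recomputed *after* the
behavioral decision could differ at reduced feeding — but the two-step
order keeps the closed form applicable and mirrors the reasoning that diet
choice happens on a faster timescale than effort choice.

## The food-web testbed

`foodweb_run()` embeds the behavioral model in a deliberately small
0-D lake: dissolved nutrient, phytoplankton, zooplankton, zoobenthos,
sediment detritus, an omnivorous fish (pelagic mode on zooplankton;
benthic mode on zoobenthos and detritus) and a predator fish feeding on
the omnivore. Everything is carried in a single nutrient-equivalent
biomass currency. Respiration remineralizes to the nutrient pool;
mortality and unassimilated ingestion route to detritus; detritus
mineralizes back to nutrient; external load, outflow flushing
(nutrient and phytoplankton) and detritus burial are the only exchanges
with the outside, so a configuration with those three set to zero is
exactly closed and total mass is conserved to rounding error — an
invariant the tests check over a decade of simulated days.

Numerical choices:

* **Forward Euler with dt = 1 day.** The behavioral decision is a
  per-time-step discrete choice, with the risk smoother defining the daily
  cadence; the plumbing is a balance of slow specific rates (≤ ~1 d⁻¹), so
  first-order stepping at the decision cadence is appropriate.
* **Availability limitation.** If a pool's outflows would overdraw it
  within a step, all its outflows are scaled down proportionally, which
  preserves both non-negativity and conservation.
* **Floor clipping.** Pools that were positive are floored at 1e-12 g m⁻³
  so populations remain revivable; the clipped mass is accumulated in a
  ledger entry so the conservation accounting stays exact. Pools that are
  exactly zero stay zero.
* **Temperature.** All physiological maxima (`I_max`, `u`,
  mineralization) scale with `Q10^((T - 20)/10)`, `Q10 = 2` by default.
* **Risk coupling.** The instantaneous predation rate on the omnivore is
  the predator's hunger-modulated realized clearance,
  `m_pred = f_feed_p c_p (1 - F_p) B_p`, fed through the smoother; the
  predator in turn sees only the unmitigated biomass
  `(1 - p* f_PM) B_omnivore`, so predator capture and prey mortality are
  identically the same flux. The predator has no predators of its own, so
  its optimization is solved with `m_pred_s = 0` and reduces to
  maximizing net energy gain: its `f_PM`/`f_FC` are accepted in the
  configuration but cannot affect mortality. Its benefit from the
  behavioral model is energetic — shutting feeding down when prey are
  scarce slows its starvation decline.
* **Control runs** (`obm: false`) feed maximally (`p = 0`,
  `f_feed = 1`) with the same optimal-diet step, so control fluxes equal
  the full-feeding Holling forms. Control trajectories are independent of
  `f_PM` and `f_FC`; `f_RF` is treated as a bioenergetic constant of the
  group (control metabolism is `(1 + f_RF) u`), not a behavioral lever,
  so that behavior-on and control runs share identical energy budgets at
  full feeding.

## Seasonal forcing

`seasonal_forcing()` produces a 365-day year of water temperature, light
factor and nutrient load as independent sinusoids (light clamped to
[0, 1], load to non-negative), looped identically every year so that any
interannual variability in model output is endogenous. Defaults emulate a
temperate lake: temperature 1–19 °C peaking in late July, light factor
0.1–1 peaking near the solstice, and a load pulse in winter. The
nutrient-loading scenario ladder multiplies the load by 0.25, 0.5, 1, 2
and 4. No weather stochasticity is included by design: variability
diagnostics below depend on the forcing being exactly periodic.

## Variability diagnostics and seasonal metrics

`within_year_cv()` is the coefficient of variation over the 365 days of
the across-year mean climatology (population standard deviation — the
cycle is complete, not sampled); `between_year_cv()` is the CV of the
annual means (sample standard deviation, n − 1). Both are invariant to
rescaling the series. The seasonal metrics of `scenario_metrics()` use
fixed windows on the 365-day calendar: August is days 213–243 and summer
(1 May–1 Oct) days 121–274. The chlorophyll proxy is phytoplankton
biomass times a configurable conversion (default 1); no pigment model is
attempted. In a 0-D water column the volume-weighted vertical average is
the identity, so none is applied.

## Calibrations and what they demonstrate

The package ships two reference parameterizations, both *toy*
calibrations owned by this package (no claim of numerical equivalence to
any lake or to any host ecosystem model):

* `default_config()` — a strongly piscivore-controlled web used for the
  nutrient-loading comparison. In the control model the predator pins the
  omnivore at all loads, zooplankton stay abundant, and the summer
  chlorophyll proxy responds weakly to the load ladder; with the
  behavioral model on (omnivore `f_PM = 0.9`, `f_FC = 0.675`, the
  predator at `f_PM = f_FC = 1`), mitigation releases the omnivore from
  trophic control, zooplankton are grazed down, and chlorophyll both
  increases with loading and spans a wider range than the control — the
  behavioral cascade reverses the direction of trophic control.
* `cycling_fixture()` — a calibration found by the deterministic grid
  search in `make_cycling_fixture()` and frozen under `inst/extdata/`. Its
  control run exhibits multiyear, high-amplitude fish-biomass cycles
  (between-year CV of omnivorous fish above the declared floor) driven by
  the mismatch between fast fish growth and the predator's slow decline;
  switching the behavioral model on at full trade-off strength
  (`f_PM = f_FC = 1`) damps the cycles of both fish groups. This is the
  stabilization property: risk mitigation converts predation mortality
  into reduced feeding, weakening the overshoot that sustains the cycle.

Default protocol lengths follow the spin-up-then-analyze convention: 100
simulated years with statistics over the last 50 (`analysis_fraction =
0.5`). Exploratory sweeps in the documentation use shorter runs (the
qualitative behavior is established well before year 40); the shipped
defaults keep the full protocol.

## What the synthetic testbed does and does not show

The generator-plus-simulator pair emulates the *structure* of the study
design: looped seasonal forcing, a four-level trophic chain with an
intermediate omnivore, per-group behavioral switches, and the
spin-up/analysis protocol. It does not emulate real lake physics
(no stratification, oxygen, ice, or macrophyte dynamics — `f_veg` is
accepted as a supplied factor only), real stoichiometry (single currency
instead of N/P/Si mass balances), fish life stages, or calibrated
parameter values. Passing tests therefore demonstrate the *mechanisms* —
emergent type-III-like responses, stabilization by behavior, release from
trophic control under enrichment — not quantitative predictions for any
real system.

## Known limitations

* The behavioral optimum is monomorphic: the whole population shares one
  `p*` per day. Independent individual optimization would lead to a
  (generally less favorable) Nash equilibrium; that game is out of scope.
* No energy storage: fitness is myopic, so the model concentrates fish
  foraging effort in lean winter months rather than banking summer
  surplus.
* The starvation branches follow the two-candidate comparison (feed
  maximally vs. fast fully); with a large `f_RF` and deep satiation an
  interior `p` could in principle beat both in the net-gain branch, but
  the branch rule is retained as the model's definition.
* Linear trade-off shapes throughout; diminishing-returns mitigation
  would change the sizes, not the existence, of the behavioral regions.
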