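# lakeOBM

Adaptive fish behavior for aquatic ecosystem models: a daily optimal
behavior model (OBM) for the trade-off between feeding and predation risk,
embedded in a minimal seasonal lake food web.

Process-based lake models usually assume fish feed at the maximum rate the
environment allows. That assumption makes trophic coupling rigid: simulated
fish populations can only respond numerically, which produces unrealistic
multiyear boom–bust cycles and overly strong top-down control. `lakeOBM`
replaces it with an optimality argument from behavioral ecology. Each day,
a fish population chooses a position *p* ∈ [0, 1] on a behavioral gradient
from maximal feeding (*p* = 0) to maximal predation mitigation (*p* = 1).
The trade-off is linear, controlled by three parameters: mitigation removes
up to a fraction *f*<sub>PM</sub> of predation mortality, costs a fraction
*f*<sub>FC</sub> of feeding activity, and active feeding carries a
metabolic surcharge *f*<sub>RF</sub>·*u*. With feeding activity
*f*<sub>feed</sub> = 1 − *p f*<sub>FC</sub>, gut-limited feeding level
*F* = *Q*/(*I*<sub>max</sub> + *Q*) (gut-weighted encounter
*Q* = *f*<sub>feed</sub> *f*<sub>veg</sub> *c f*<sub>gut</sub> *R*),
assimilation *g* = *a f*<sub>feed</sub> *f*<sub>veg</sub> *c R* (1 − *F*),
mortality *m*<sub>tot</sub> = *m*<sub>nat</sub> + (1 − *p f*<sub>PM</sub>)
*m*<sub>pred.s</sub> and metabolism *u*<sub>tot</sub> = (1 + *f*<sub>RF</sub>
*f*<sub>feed</sub>) *u*, the population maximizes Gilliam's-rule fitness

  *W*(*p*) = (*g* − *u*<sub>tot</sub>) / *m*<sub>tot</sub>

whenever feeding can pay for itself, and net energy gain
*W* = *g* − *u*<sub>tot</sub> when it cannot (starvation logic: feed
maximally while *g*<sub>pot</sub> − *u*<sub>pot</sub> > −*u*, stop feeding
and mitigate fully below that threshold). The maximizer *p*\* is available
in closed form — the stationary condition is a quadratic in *p* — and is
verified against a brute-force grid oracle in the tests. Optimizing *p*
produces an *emergent* functional response: Holling type III-like when
mitigation is fully costly, with a non-monotonic branch when mitigation is
cheap and predation high.

The package provides:

* `optimal_behavior()`, `fitness()`, `functional_response()` and the
  component rates (`feeding_level()`, `ingestion()`, `total_mortality()`,
  `smooth_predation()`, `total_metabolism()`) — the single-prey OBM;
* `optimal_diet()`, `allocate_modes()`, `diet_then_behavior()` — exact
  greedy diet-breadth selection under shared gut saturation, feeding-mode
  allocation, and the two-step diet-then-behavior decision;
* `foodweb_run()` — a mass-conserving 0-D lake food web (nutrient,
  phytoplankton, zooplankton, zoobenthos, sediment detritus, omnivorous
  and predator fish) on looped 365-day sinusoidal forcing
  (`seasonal_forcing()`), with a per-group OBM switch;
* `within_year_cv()`, `between_year_cv()`, `scenario_metrics()` — the
  variability decomposition and seasonal food-web metrics;
* `tradeoff_sweep()`, `loading_ladder()`, `make_cycling_fixture()` —
  scenario drivers, and a command-line tool (`inst/exec/lakeobm`) with
  verbs `run`, `sweep`, `loading`, `response`, `fixture`.

## Worked example

Solve the behavioral optimum for a fish that encounters moderate food
under tangible predation risk:

```r
library(lakeOBM)
env <- feeding_env(R = 2, c = 0.5, I_max = 0.05, a = 0.7, u = 0.005,
                   m_nat = 5e-4, m_pred_s = 0.01)
optimal_behavior(env, tradeoff_params(f_PM = 1, f_FC = 1, f_RF = 0.3))
#> Optimal behavior [normal]
#>   p* = 0.933624, f_feed = 0.0663757, feeding level F = 0.570357
#>   g = 0.0199625 d^-1, u_tot = 0.00509956 d^-1, m_tot = 0.00116376 d^-1, W = 12.7715
```

The population puts 93 % of its effort into risk mitigation: at this food
level the marginal fitness value of safety exceeds that of a fuller gut.
It still assimilates 0.02 d⁻¹ — about four times its metabolic cost —
while cutting predation mortality by 93 %.

Switching the behavior on stabilizes the food web. On the shipped cycling
calibration (`cycling_fixture()`), 100 simulated years with statistics
over the last 50:

```r
fx <- cycling_fixture()
off <- fx$cfg; off$omnivore$obm <- FALSE; off$predator$obm <- FALSE
r_off <- foodweb_run(off, years = 100)
r_on  <- foodweb_run(fx$cfg, years = 100)    # f_PM = f_FC = 1
between_year_cv(analysis_series(r_off, "omnivore"))
#> [1] 1.520083
between_year_cv(analysis_series(r_on, "omnivore"))
#> [1] 0.8400058
```

The control model cycles through multiyear booms and crashes of
omnivorous fish biomass (between-year CV 1.52); switching the behavioral
model on at full trade-off strength roughly halves the interannual signal
(CV 0.84; the predator's between-year CV falls from 0.98 to 0.45) while
the seasonal cycle remains.

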