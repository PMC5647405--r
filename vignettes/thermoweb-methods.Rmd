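---
title: "Temperature-forced food-web dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-forced food-web dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoweb)
```

`thermoweb` models a fished marine food web as a mass-balanced baseline
extended in time by foraging-arena consumption dynamics, with each
predator's consumption scaled by a species-specific thermal response. This
vignette documents the model equations, the assumptions behind them, the
tunable parameters, and the numerical and design choices, so that results
can be interpreted knowing exactly what was and was not modelled.

## The mass-balance baseline

Each functional group $i$ satisfies, at the reference year,

$$B_i \left(\tfrac{P}{B}\right)_i EE_i \;=\; \sum_j B_j
\left(\tfrac{Q}{B}\right)_j DC_{ij} \;+\; Y_i,$$

production equals predation plus catch, with the ecotrophic efficiency
$EE_i$ absorbing the fraction of production that is consumed or caught
within the system. Biomass accumulation and migration terms are fixed at
zero; the configuration schema reserves room for them but the dynamics
never use them. Per group exactly one of $\{B, EE\}$ may be unknown;
unknown biomasses are solved jointly by linear elimination (a singular
system, e.g. a self-feeding group whose balance coefficient cancels, is
reported with the offending group names). A solution with any $EE \notin
[0,1]$ is flagged unbalanced but returned, since diagnosing an infeasible
parameterisation is part of normal model building. Other (non-predation,
non-fishing) mortality is $M0_i = (P/B)_i (1 - EE_i)$.

Detritus pools are passive: they receive the unassimilated fraction of all
consumption (default assimilation 0.8) plus non-predation deaths, lose
detritivory and catch, and are closed at baseline by a linear export rate
(or a constant import when detrital supply falls short) calibrated so the
baseline pool is stationary. Detritus $EE$ is reported as a diagnostic and
never constrains the balance.

## Foraging-arena consumption

Consumption on each predator–prey link follows the foraging-arena form

$$Q_{ij} = \frac{a_{ij}\, v_{ij}\, B_i\, P_j\, T_i\, T_j\, M_{ij}}
{v_{ij} + v_{ij} T_i M_{ij} + a_{ij} M_{ij} P_j T_j / D_j}
\times f_{env,j}(t),$$

with search rate $a$, vulnerability exchange rate $v \in [1, \infty)$,
prey and predator pools $B_i$ and $P_j$, relative feeding times $T$,
mediation $M$ (fixed at 1; the hook is retained), handling time $D_j$, and
the thermal scaling $f_{env}$. Two conventions deserve comment:

* **The predator pool appears in the saturation term.** Printed variants
  of this equation sometimes carry the prey pool there; the standard
  derivation of vulnerable-pool exchange uses the predator pool, and the
  calibration below assumes it. The prey-pool variant is available in
  `consumption_rate(literal_pool = TRUE)` for comparison.
* **Handling time defaults to $D = 1$.** With $T = M = 1$ the denominator
  is $2v + aP/D$. If the saturation term is removed entirely
  ($D = \infty$), $v$ cancels algebraically and every link collapses to
  Lotka–Volterra ($Q = aB_iP_j/2$) — vulnerability would then have no
  dynamical meaning and could not be estimated. $D = \infty$ is still
  allowed per link, and is deliberately used in the synthetic generator
  for the zooplankton, whose prey turnover is far too fast for predator
  saturation to matter ($v \cdot B_{prey} > Q_0/D$ must hold for the
  calibration to be feasible; fast links violate it at any moderate $v$).

Search rates are not free parameters: `calibrate_arena()` solves each link
in closed form, $a = 2 v Q_0 / (P_0 (v B_0 - Q_0/D))$, so that consumption
at the baseline state reproduces the mass-balance consumption exactly.
Consequently the baseline is an exact fixed point of the dynamics when all
forcings are at their reference values — hindcast deviations are driven
entirely by forcing, vulnerabilities and the thermal responses, never by
integration drift (the test suite verifies < 1e-6 relative drift over 50
simulated years).

Vulnerability is the behavioural lever: $v \to 1$ makes predation
insensitive to predator abundance (bottom-up control), large $v$
approaches donor-independent Lotka–Volterra coupling (top-down control),
and 2 is the conventional neutral default.

## Thermal responses

Each species' thermal niche is a two-sided Gaussian: the consumption
scaling equals 1 exactly at the optimum $T_{opt}$ and declines as
$\exp(-(T - T_{opt})^2/2\sigma^2)$ with separate $\sigma$ below and above
the optimum, honouring asymmetric tolerances (a pooled-σ symmetric mode
exists for sensitivity checks). Niches can be built from envelope
temperatures: $T_{opt}$ is the mean of the 10th and 90th preferred
percentiles and the side σs place the reported min/max `k_sigma` standard
deviations out. `k_sigma = 2` by default: reported extremes are treated as
~2σ excursions, a choice the envelope sources do not pin down; explicit
σ columns in `thermal.csv` override it. Degenerate zero-width sides get a
0.5 °C floor. Multi-species groups aggregate envelope parameters as
weighted geometric means (biomass or catch weights), with sub-zero
temperatures shifted positive before log-averaging; juvenile pools can be
shifted rigidly warmer (default +1 °C). Plankton-type groups, which lack
usable tolerance data, are given the historical mean temperature as
optimum with very wide σ (10 °C), making them effectively
temperature-neutral.

The response scales each predator's consumption; by default it also scales
producer production (`producer_env = TRUE`), since the alternative —
temperature acting on consumers only — is equally defensible; both are
supported and switchable. Note the response is an *absolute* scaling: a
niche whose optimum sits far from the simulated temperatures imposes a
chronic production deficit that no feedback can fully offset, so webs
parameterised that way decline from their baseline. That is a feature of
the formulation, not an artefact, but it matters when building synthetic
systems (see below).

Producers grow logistically with carrying capacity `producer_cap` (default
10) times baseline biomass, the growth rate calibrated so the baseline is
an exact fixed point despite the self-limitation. Linked juvenile/adult
pairs exchange a first-order maturation flow measured as a deviation from
its baseline value (rate `stanza_rate`, default 0.5 yr⁻¹), which keeps the
balanced state stationary while coupling the pools' excursions; full
age-structured (delay-difference) stanzas are out of scope.

## Integration

A fixed-step classical 4th-order Runge–Kutta scheme advances the system
with 12 steps per year by default; catches are integrated as auxiliary
states with the same weights, and annual biomass is the trapezoidal mean
over the sub-steps. Fixed stepping was chosen over adaptive integration
for bit-for-bit reproducibility; halving the step changes trajectories by
well under 0.1 %. Biomass is floored at 1e-12 to keep log-residuals
defined through transient collapses. The optional feeding-time adaptation
($T_j$ multiplied annually by $1 - \alpha + \alpha\, q_{target}/
q_{realised}$, clamped to [0.1, 2]) is off by default ($\alpha = 0$)
because no published update rule accompanies the concept; enabling it
makes starved predators forage longer.

## Fitting

The objective is the weighted log sum of squares
$SS = \sum_s w_s \sum_t (\ln o_{st} - \ln \hat{y}_{st})^2$ over observed
biomass and catch series (weights default to 1; pedigree-derived weights
can be supplied per series). Free parameters are per-predator
vulnerabilities — "by predator": one value shared by all prey links of
that predator — transformed as $v = 1 + e^\theta$ so the fitted domain is
$(1, \infty)$, and the knot values of a primary-production anomaly spline,
$e^\theta > 0$, interpolated monotone-safely (Fritsch–Carlson Hermite in
log space) through knots evenly spaced over the fit window and applied as
a multiplier on producer production.

`stepwise_fit()` evaluates a ladder of configurations: the baseline (no
fishing variation, $k = 0$), fishing only ($k = 0$), anomaly-only rows,
and vulnerability rows with predators entering greedily by their
single-predator SS reduction (an exhaustive subset mode exists for small
webs). Each configuration is minimised by Nelder–Mead (relative tolerance
1e-8, up to 3 starts) warm-started from its nested neighbours; in
particular a configuration inherits the exact solution of its
one-predator-smaller neighbour with the new predator at the neutral
$v = 2$, which guarantees the minimum SS never increases along genuinely
nested chains. One-parameter searches bracket on a coarse grid before
golden-section refinement. Non-converged configurations are flagged and
retained, not dropped. Model comparison uses least-squares
$AIC = n\ln(SS/n) + 2k$, the small-sample $AICc$, and Akaike weights;
percent SS reduction is reported against the baseline row of the same
candidate set, so runs with and without temperature forcing each carry
their own reference.

## Uncertainty and validation

Monte Carlo trials perturb each group's supplied basic inputs (B, P/B,
Q/B, EE) independently and uniformly within ±CV — the uniform convention
matches how input pedigrees are commonly interpreted; a Gaussian switch
would be trivial but is not exposed. Each trial re-balances, rejects
infeasible or unbalanced draws, recalibrates search rates with the fitted
vulnerabilities held fixed (re-estimating vulnerabilities inside trials is
explicitly out of scope), re-simulates, and accumulates until the
requested number of accepted trials (default 200) yields empirical 5th/
50th/95th percentile envelopes. The P/B CV is capped at 0.1 in pedigree
mode: biomass and P/B uncertainty compound multiplicatively and wider P/B
intervals inflate the envelopes disproportionately. Uncertainty is
propagated after fitting, on the fixed best-fit arena; re-ordering these
stages would feed input uncertainty into the vulnerability estimates
themselves and is left as future work.

Hold-out validation splits observation series chronologically; the named
schemes on a 29-year record reserve the final 7, 5 or 3 years (fit spans
of 22, 24, 26 years). Skill is root-mean-square deviation on the natural
scale, per series and pooled over all residuals.

## Scenarios

Future forcing is composed additively. Depth-integrated temperature is
surface temperature minus a constant surface-to-bottom offset (0.61 °C for
the west-of-Scotland shelf; a multiplicative mode exists because the
phrase "scaling to the difference" is ambiguous, but subtraction is the
default and the documented interpretation). Oscillation indices are
projected by time-reflection around a pivot year — default 2012, the end
of the last warm phase, configurable to 2007 or elsewhere — wrapping by a
62-year recurrence when the reflection runs off the record. Future
temperature is then last-historical-DIT + warming anomaly + interannual
variability + oscillation. The variability term is a seeded Gaussian draw
whose standard deviation follows a 3-year moving-window estimate of the
detrended historical residual SD, recycled over the projection; the
conversion of a "moving-average historical SD" into year-specific noise is
an interpretation, documented as such, and can be disabled. Warming
anomalies are user-supplied series; synthetic stand-ins for four RCP-like
intensities (≈ +1.0, +1.8, +2.2, +3.7 °C by 2100, the low scenario
stabilising mid-century) are provided because downloading climate
ensembles is out of scope. An `fmsy_table.csv` fixture ships the published
status-quo and MSY fishing mortalities for the west-of-Scotland target
stocks.

Scenario fishing mortalities apply as a step change at the scenario start
by default — matching how such projections are usually run — with an
optional ±15 %-per-year ramp reflecting how management actually moves F.
Cumulative summaries report rounded percent decreases,
$\mathrm{round}(100\,(x_0 - x_1)/x_0)$.

## The synthetic generator — and what passing its tests does not show

`make_web()` builds a 6-group shelf-sea caricature (phytoplankton,
detritus, zooplankton, a zooplanktivorous forage fish, detritivorous
benthos, a fished piscivore) whose balance is feasible by construction
(max EE ≈ 0.7), plus a 3-group minimal chain. Niches contrast a boreal
stenotherm (the predator: optimum 9.3 °C, upper σ 2 °C, sitting on its
warm flank late in the series) with a eurytherm (forage fish: optimum
11 °C, σ 6/4 °C). These optima are deliberately close to the reference-era
temperatures: because the thermal scaling is absolute, niches far from the
simulated climate would impose immediate chronic deficits and the web
would have no stable reference behaviour to fit against.

`make_observations()` runs the forward model over 29 years under a planted
top-down predator ($v = 50$), a planted 3-knot production anomaly
(multipliers 1.1, 0.9, 1.05 — strong enough to matter, weak enough not to
crash the chain), fishing mortality trending up 30 %, and a temperature
series with a 0.03 °C yr⁻¹ trend, a 62-year oscillation (amplitude
0.3 °C) and white noise (SD 0.15 °C); observations are the trajectories
times lognormal noise (mean 1, CV 0.1 by default). Everything derives from
one seed.

The generator shares its observation model (multiplicative lognormal
noise) and its dynamics with the estimator, so recovery tests demonstrate
*internal consistency* — the fitting machinery finds planted structure
when the model is correctly specified — and nothing about structural
misspecification, unmodelled age structure, observation bias, or real
survey error covariance. Problem sizes in the test suite (6 groups, 29
years, 20 replicate noise draws for recovery, 200 Monte Carlo trials) were
chosen as the smallest systems that exercise every code path with
comfortable statistical margins.

## Known limitations

Temperature acts only on consumption (and optionally producer growth):
metabolic P/B shifts, growth, recruitment and distribution responses are
not modelled. Fleets are aggregated to one F per group; there is no
spatial structure; multi-stanza pools use the simplified deviation-flow
linkage, not delay-difference dynamics. The mediation hook is fixed at 1.
Feeding-time adaptation, when enabled, uses a plausible but unpublished
first-order rule. These boundaries mirror the scope of the modelling
tradition this package implements.

## A minimal session

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1)
sim  <- make_observations(spec)
fit  <- stepwise_fit(sim$web, sim$sol, sim$forcing, sim$observed,
                     max_v = 2, max_spline = 3)
fit$table

arena <- calibrate_arena(sim$sol, v = sim$web$vulnerability,
                         d = sim$web$handling)
ped  <- pedigree_fixed(sim$web, cv = 0.1)
env  <- monte_carlo(sim$web, sim$sol, arena, sim$forcing, ped,
                    n_trials = 200, seed = 1)
```
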