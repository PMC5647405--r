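# thermoweb

Temperature-forced trophic food-web modelling, fitting and projection in R.

`thermoweb` is for ecosystem and fisheries modellers who want to ask how a
fished food web responds to warming: it couples an Ecopath-style
mass-balance baseline to foraging-arena biomass dynamics in which every
predator's consumption is scaled by a species thermal response, fits the
resulting model to observed biomass/catch time series by stepwise AIC
search, quantifies input uncertainty by Monte Carlo, validates by
chronological hold-out, and projects forward under combined fishing
(status quo vs maximum sustainable yield) and warming (RCP-style)
scenarios.

## The model

A balanced baseline satisfies, per group *i*,

    B_i (P/B)_i EE_i = Σ_j B_j (Q/B)_j DC_ij + Y_i

(production = predation + catch; unknown biomass or ecotrophic efficiency
EE solved by linear elimination). Dynamics follow foraging-arena
consumption per predator–prey link,

    Q_ij = a v B_i P_j T_i T_j M / (v + v T_i M + a M P_j T_j / D) × f_env(T, t)

where the vulnerability `v ∈ [1, ∞)` sets bottom-up (v ≈ 1) versus
top-down (v > 2) control, the search rate `a` is calibrated in closed form
so the baseline is an exact fixed point, and `f_env` is a two-sided
Gaussian thermal niche equal to 1 at the species optimum. Fitting
estimates per-predator vulnerabilities and a positive production-anomaly
spline by minimising the weighted log sum of squares, ranked by
AIC/AICc/Akaike weights. See `vignette("thermoweb-methods")` for the full
account.

## Worked example

Generate a synthetic 6-group shelf web with a planted top-down predator
(v = 50) and a planted 3-knot production anomaly, then recover both:

```r
library(thermoweb)

spec <- synthetic_spec(seed = 1)   # 29 years, noise CV 0.1
sim  <- make_observations(spec)
sim$sol
#> ecopath_solution ( balanced )
#>               biomass     ee   m0   f0
#> phytoplankton    30.0 0.7000 6.00 0.00
#> detritus        150.0 0.3135 0.00 0.00
#> zooplankton      15.0 0.2600 5.92 0.00
#> foragefish        6.0 0.3077 0.90 0.10
#> benthos          10.0 0.0680 2.33 0.05
#> predator          1.5 0.6000 0.20 0.30

fit <- stepwise_fit(sim$web, sim$sol, sim$forcing, sim$observed,
                    max_v = 2, max_spline = 3)
fit$table[1:5, ]
#>                            name k_params    ss ss_reduction_pct   aic akaike_weight
#> 1 fishing + 2 Vs + 3 PP_anomaly        5  2.25               97 -1065      1.00e+00
#> 2        fishing + 3 PP_anomaly        3  2.99               96 -1004      4.39e-14
#> 3 fishing + 1 Vs + 3 PP_anomaly        4  2.98               96 -1002      2.51e-14
#> 4 fishing + 2 Vs + 2 PP_anomaly        4 13.06               83  -660      8.79e-89
#> 5 fishing + 2 Vs + 1 PP_anomaly        3 14.20               81  -642      1.46e-92

round(fit$best$v_by_predator, 2)
#> foragefish   predator
#>       2.96     752.39
cor(fit$best$anomaly_series, sim$truth$anomaly_series)
#> [1] 0.985
```

The best-AIC configuration carries 2 vulnerabilities + 3 spline points
(k = 5), classifies the planted predator as top-down (fitted v ≫ 2; the
likelihood is flat above ~50, so the magnitude is not interpretable — the
classification is), and recovers the anomaly shape with correlation 0.985
against truth. Columns mirror the conventional stepwise comparison table:
parameters estimated, SS, percent SS reduction versus the unforced
baseline, AIC and Akaike weight.

Downstream stages follow the same pattern: `monte_carlo()` for 5–95 %
pedigree envelopes, `validation_split()`/`rmsd()` for hold-out skill,
`mirror_amo()`/`build_future_temperature()`/`project_scenario()` for
climate-fishing projections, and `run_pipeline()` to execute the whole
chain from one seed with CSV/JSON outputs. The published status-quo and
MSY fishing mortalities for the west-of-Scotland target stocks ship in
`inst/extdata/fmsy_table.csv`.

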