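# nitroxsim

Abiotic nitrogen chemistry and process metrics for acidic ammonia
oxidation (nitritation) reactors.

## The problem

Nitrifying high-strength, alkalinity-limited streams such as
source-separated urine at pH ≈ 5 selects for acid-tolerant
ammonia-oxidizing bacteria, but it also switches on purely *chemical*
nitrite oxidation: free nitrous acid (HNO₂), abundant at low pH,
disproportionates to the volatile radicals NO and NO₂, which are partly
re-oxidized and hydrolyzed to nitrate and partly stripped out of the
reactor as harmful gases. For engineers and researchers running or
modeling such reactors, the key questions are how much of the observed
nitrate production the abiotic chemistry alone explains, how much
nitrogen leaves as gas, and which conditions (pH, DO, nitrite level,
salinity) make the process fragile.

`nitroxsim` implements that chemistry as a tested R package:

* **Speciation** — NH₄⁺/NH₃ and NO₂⁻/HNO₂ acid–base pairs with
  temperature-dependent dissociation constants and Davies
  activity correction:
  `NH₃-N = TAN·r/(1+r)`, `r = 10^(pH−pKa′)`;
  `HNO₂-N = TNN/(1 + 10^(pH−pKa)/γ)`.
* **Reaction network** — mass-action kinetics for
  `2HNO₂ ⇌ NO + NO₂ + H₂O`, `2NO + O₂ → 2NO₂`,
  `2NO₂ + H₂O ⇌ HNO₂ + NO₃⁻ + H⁺`, with N₂O₃ treated as a quasi-steady
  intermediate partitioned between decomposition and reaction with NH₃
  (`N₂O₃ + NH₃ → N₂ + HNO₂ + H₂O`), plus first-order kLa stripping of
  NO and NO₂.
* **Driven CSTR** — `dC/dt = (Q/V)(C_in − C) + source + chemistry +
  stripping` with measured (or synthetic) flow, influent TAN, pH, DO
  and temperature as exogenous drivers and the observed
  ammonia-to-nitrite conversion imposed as a source term; biology is
  deliberately off.
* **Metrics** — Nash–Sutcliffe model efficiency
  `E = 1 − Σ(yᵐ−y)²/Σ(yᵐ−ȳᵐ)²`, nitrite accumulation ratio
  `NAR = 100·TNN/(TNN+NO₃)`, nitrogen-loss fraction, HRT/SRT and
  washout growth rate `µ = 1/SRT`, alkalinity-limited conversion.
* **Activity factors** — Monod DO/NH₃ limitation, non-competitive HNO₂
  inhibition `K_I/(K_I+S)`, threshold-linear salinity factor.
* **Synthetic operations** — a seeded generator of realistic reactor
  timelines (on–off pH and DO control, influent tank changes, and the
  four classic disturbances: influent stop, aeration stop, overpumping,
  overheating) so everything is testable without plant data.

The shipped chemical rate constants are order-of-magnitude literature
placeholders (see `?chem_kinetics_params`); all structural results
(conservation, balance closure, monotonicity) are independent of them.

## Worked example

```r
library(nitroxsim)

# speciation at reactor conditions (urine-like salinity)
speciate(TAN = 1800, TNN = 900, pH = 5.0,
         ctx = ionic_context(conductivity = 30))
#> $NH3_N  0.0748   $NH4_N  1800   $HNO2_N 14.5   $NO2_N  885   (mg-N/L)

# a 20-day synthetic scenario through the driven CSTR
cfg <- scenario_config(duration = 20, dt = 0.02, seed = 42)
tl  <- generate_timeline(cfg)
res <- simulate_reactor(tl)
res
#> CSTR simulation: 1001 output times, 20 d
#>   final TAN 462.0, TNN 390.2, NO3-N 46.2 mg-N/L
#>   influent N 44404.3 mg; gaseous loss 14923.0 mg (NO 671.1, NO2 1.3, N2 14250.6)
#>   N balance relative error 1.4e-14

# goodness of fit against (here: noisy synthetic) measurements
meas_TNN <- add_measurement_noise(res$series$TNN, 20, seed = 1)
meas_NO3 <- add_measurement_noise(res$series$NO3_N, 2, seed = 2)
fit_to_measurements(res, meas_TNN, meas_NO3)
#> model efficiency: TNN E = 0.958, nitrate E = 0.985 (n = 1001, 1001)

# interpretation aids
nitrite_accumulation_ratio(390.2, 46.2)       # 89.4 % as nitrite
net_growth_rate_from_srt(1.6)                 # 0.625 -> reported 0.6 1/d
activity_factors(HNO2 = 14.5, DO = 5, NH3 = 0.075, EC = 30)$combined
#> 0.103  (HNO2 inhibition dominates at pH 5)
```

The free nitrous acid value is why acidic nitritation is delicate: at
500 mg-N/L nitrite, dropping below pH 4.2 already means more than
40 mg-N/L HNO₂ — past the tolerance of even acid-tolerant ammonia
oxidizers.

A thin CLI over the same functions is installed at
`inst/cli/nitroxsim.R` (subcommands `speciate`, `synth`, `simulate`,
`metrics`, `factors`).

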