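---
title: "Modeling the abiotic nitrogen chemistry of acidic nitritation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the abiotic nitrogen chemistry of acidic nitritation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroxsim)
```

## Scope and model structure

`nitroxsim` models what happens to nitrogen in an aerated,
continuously fed stirred-tank reactor that nitritates a high-strength,
alkalinity-limited stream (typically source-separated urine) at acidic
pH. The package's central assumption mirrors how such systems are
analyzed in practice: **the biology is not simulated**. The observed
ammonia-to-nitrite conversion is imposed as a source term, and the
model then asks how much of the nitrite is converted onward — to
nitrate or to volatile nitrogen oxides — by purely chemical reactions.
pH, dissolved oxygen, temperature and conductivity are *exogenous
drivers* read from the operation timeline, never solved for: there is
no charge balance and no alkalinity ODE. This reproduces the structure
in which such models are actually run (the pH record comes from the
plant, not from the model) and avoids inventing a pH model that the
available information cannot constrain.

### Speciation

Both acid–base pairs are assumed at instantaneous equilibrium:

* ammonium: pKa(T) = 0.09018 + 2729.92 / T[K]
* nitrous acid: ln Ka(T) = −2300 / T[K]

These are the classical temperature functions of the nitrification
literature; both are configurable coefficient pairs in
`speciation_constants()`. Ionic-strength correction uses the Davies
equation (A = 0.509, linear term 0.3), applied to the charged species
only; pH is interpreted as hydrogen-ion *activity*, i.e. what a glass
electrode reports. When no ionic strength is supplied it is estimated
from conductivity as I = 0.016 · EC (mol/L per mS/cm), the common
empirical rule for mixed electrolytes — both the factor and the choice
of correction are exposed in the API because neither is uniquely
determined for urine matrices.

Speciation is conservative by construction (free + ionized = total,
exactly), and the free fractions are strictly monotone in pH. At 25 °C
the defaults give pKa(NH₄⁺) ≈ 9.25 and pKa(HNO₂) ≈ 3.35, which places
the operationally critical bound where practitioners expect it: at
500 mg-N/L total nitrite, pH 4.2 already corresponds to > 40 mg-N/L
free nitrous acid.

### The chemical nitrite oxidation network

Five reactions are modeled with mass-action kinetics on the molar
scale (concentrations handled as mg-N/L at the interface, converted
internally):

1. `NO₂⁻ + H⁺ ⇌ HNO₂` — instantaneous, via the speciation layer;
2. `2 HNO₂ ⇌ NO + NO₂ + H₂O` — forward rate k·[HNO₂]², reverse
   k·[NO][NO₂];
3. `2 NO + O₂ → 2 NO₂` — k·[NO]²[O₂], zero under anoxia;
4. `2 NO₂ + H₂O ⇌ HNO₂ + NO₃⁻ + H⁺` — forward k·[NO₂]²; the reverse
   path (first order in each of HNO₂, NO₃⁻ and H⁺ activity) defaults
   to zero, since hydrolysis is essentially irreversible above pH 2;
5. `N₂O₃ → NO + NO₂` and `N₂O₃ + NH₃ → N₂ + HNO₂ + H₂O` — treated as
   one quasi-steady pathway (below).

**N₂O₃ handling.** Dinitrogen trioxide forms rapidly from NO + NO₂ and
either decomposes straight back or reacts with free ammonia. Carrying
it as a state variable would add an extremely stiff, observationally
unconstrained species, so it is eliminated by a quasi-steady-state
argument: the formation flux k_f·[NO][NO₂] is partitioned with the
branching fraction

φ = k_NH₃·[NH₃] / (k_dec + k_NH₃·[NH₃]),

and only the ammonia branch has a net effect (the decomposition branch
returns its reactants). The branch can be disabled entirely
(`nh3_branch = FALSE`), in which case the pathway is inert. At pH ≈ 5
free ammonia is a 10⁻⁵ fraction of TAN, so φ is small; with the
shipped constants the branch is nevertheless a significant nitrogen
sink over long runs, and users who consider the dinitrogen route
negligible for their system should switch it off.

**Rate constants.** All constants are configurable with units recorded
alongside values (`chem_kinetics_params()`, YAML round-trip via
`read_kinetics_config()`). The shipped defaults are order-of-magnitude
values assembled from the aqueous nitrogen-oxide literature and are
explicitly placeholders: primary sources disagree and the appropriate
effective constants depend on matrix and temperature. Every structural
guarantee of the package — nitrogen conservation, balance closure,
detailed-balance fixed points, monotonicity of nitrate production in
HNO₂ and DO — holds for *any* non-negative constants, and the test
suite exercises both the defaults and a numerically tame set.

**Gas stripping** of NO and NO₂ is first-order, flux = kLa·C, with
zero gas-phase backpressure (open, vigorously aerated reactor). When
the DO driver indicates the aerator is off (DO ≤ 0.1 mg/L) the fluxes
are scaled by `aeration_off_factor` (default 0.1) to represent
residual surface transfer. N₂ from the ammonia branch is booked as an
immediate gaseous loss (its solubility and inertness make dissolved
tracking pointless).

### The driven CSTR

For each dissolved pool,

dC/dt = (Q/V)(C_in − C) + imposed nitrite source/sink + chemistry + stripping,

with the imposed source f_ox·Q·TAN_in/V moved from the TAN pool to the
nitrite pool. The conversion fraction f_ox defaults to 0.5 — the value
dictated by the roughly 1:1 molar alkalinity:TAN ratio of stored urine
(two protons are released per mol N oxidized, so conversion stalls at
alkalinity/2·TAN; see `alkalinity_limited_fraction()`). Whether the
real conversion was constant or tracked the measured TAN cannot be
decided from operating records alone; f_ox therefore accepts either a
scalar or a full series.

Driver interpolation follows signal character: zero-order hold for
pump and control signals (Q, TAN_in, f_ox), piecewise-linear for pH,
DO, temperature and conductivity. The initial condition defaults to
nitrogen-free water at the timeline's initial pH/DO/T, resembling an
enrichment start-up; it is configurable.

Cumulative influent, effluent, stripped and N₂ masses are
co-integrated as auxiliary states, so the whole-run nitrogen balance
(influent = Δstorage + effluent + stripped + N₂) closes to solver
precision rather than to output-grid quadrature error. The test suite
requires closure within 10⁻⁴ relative on arbitrary synthetic
timelines; in practice it closes near machine precision.

### Numerical choices

* Integration: `deSolve::lsoda` with an analytic Jacobian of the
  chemical terms (verified against a central-difference Jacobian in
  the tests). The network is genuinely stiff with literature-scale
  constants; the analytic Jacobian roughly quadruples throughput.
* Tolerances: rtol 10⁻⁶; atol 10⁻⁹ mg-N/L for closed-system batch
  integrations, 10⁻⁶ for driven reactor runs whose states span five
  orders of magnitude.
* Negative excursions below tolerance are clipped to zero (with a
  warning if they exceed ten times atol).
* The fixed-step explicit-Euler integrator used as a cross-check in
  the tests is written against the public one-step API and shares no
  code with the solver path.

## The synthetic-operations generator

`generate_timeline()` produces the drivers of a plausible acidic
nitritation campaign, as a pure function of a seeded configuration:

* pH oscillates in a 4.9–5.0 control band, emulating on–off influent
  dosing (alkaline urine raises pH; ammonia oxidation lowers it). The
  dynamics are phenomenological — linear drift at configurable rates —
  deliberately independent of the chemistry module under test.
* Q toggles with the dosing phase, sized so the mean flow meets a
  target HRT drawn from 1.6–10 d.
* Influent TAN is piecewise constant between 1000 and 3500 mg-N/L with
  steps at tank changes every 10–30 d.
* DO follows a triangular on–off wave between 4 and 6 mg/L;
  temperature sits at 25 °C; conductivity performs a mean-reverting
  walk within 25–40 mS/cm.
* Four disturbance classes can be injected (`inject_disturbance()`):
  influent stop (Q = 0, pH relaxing toward a floor of 4), aeration
  stop (DO = 0 for 3–15 h), overpumping (one reactor volume per half
  day, pH rising toward 8.5) and overheating (toward 33 °C), each with
  exponential relaxation and recovery.

What the generator does **not** emulate: microbial community dynamics
and their feedback on rates, influent composition beyond TAN,
measurement dropout and sensor drift (only additive Gaussian noise,
`add_measurement_noise()`), and any correlation between pH excursions
and the chemistry they would cause in a real reactor (pH is imposed,
not emergent). Passing tests on synthetic timelines therefore
demonstrate correctness of the *solver and accounting*, not fidelity
of any particular rate-constant choice to a specific plant.

The default scenario is 100 d at 0.01 d resolution. The test suite and
the acceptance script use scaled-down runs — 3–5 d at 0.02 d for the
50-timeline balance-closure property, 20 d at 0.02 d for the headline
scenario — sizes chosen to keep the whole suite comfortably
interactive while still spanning many control cycles and several
retention times.

## Activity factors

The respirometric interpretation helpers are descriptive utilities and
are intentionally not wired into the reactor model (whose chemistry is
abiotic):

* HNO₂ inhibition: non-competitive, K_I/(K_I + S). This form
  reproduces a 91 % activity loss at S = 30 mg-N/L with
  K_I = 2.8 mg-N/L, the upper end of the range reported for
  conventional ammonia oxidizers (0.07–2.8 mg-N/L). Irreversible HNO₂
  toxicity at higher concentrations is *not* modeled and is flagged as
  a caveat wherever factors are reported.
* DO and NH₃ limitation: Monod, with defaults K_S,DO = 0.8 mg-O₂/L
  (the estimate for acid-tolerant ammonia oxidizers) and
  K_S,NH₃ = 0.001 mg-N/L (sub-microgram affinity).
* Salinity: only a threshold (20 mS/cm) is well constrained by
  observation, so the factor is threshold-linear with a configurable
  slope; the default 2.5 %/mS·cm keeps partial activity across the
  conductivity range of nitrified urine. The pH-activity envelope
  above pH 8 is left unmodeled: no functional form can be justified
  from short-term data, and guessing one would suggest unearned
  precision.
* Factors combine multiplicatively (`combined_activity()`), the
  activated-sludge-model convention.

## Limitations

* Quantitative gas-loss and nitrate-production predictions inherit the
  placeholder status of the shipped rate constants; calibrate against
  the primary kinetic literature or plant data before relying on
  magnitudes.
* No carbonate system, CO₂ stripping, or multi-component ion pairing;
  the Davies correction is a single-parameter approximation that
  degrades above I ≈ 0.5 mol/L, the upper end of urine strength.
* No N₂O pathway, no headspace chemistry, no NO toxicity feedback on
  biology (there is no biology).
* The nitrogen-loss metric counts dissolved N in and out; it can be
  computed from cumulative masses (default) or averaged concentration
  ratios — the two differ under strongly varying flow, and both are
  provided because operating reports rarely say which was used.

## A minimal run

```{r example, eval = FALSE}
cfg <- scenario_config(duration = 20, dt = 0.02, seed = 42)
tl <- generate_timeline(cfg)
res <- simulate_reactor(tl)
res
nitrogen_loss_fraction(res)
fit_to_measurements(res,
                    add_measurement_noise(res$series$TNN, 20, seed = 1),
                    add_measurement_noise(res$series$NO3_N, 2, seed = 2))
```
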