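# Shared fixtures: a numerically tame kinetic parameter set for oracle
# comparisons, and an independent fixed-step explicit-Euler integrator
# used to cross-check the adaptive stiff solver.

mild_kinetics <- function(...) {
  chem_kinetics_params(k_hno2_disp = 2e4, k_no_no2_recomb = 1e5,
                       k_no_oxidation = 1e8, k_no2_hydrolysis = 1e5,
                       k_no3_recomb = 10, k_n2o3_formation = 1e5,
                       k_n2o3_decomp = 1e3, k_n2o3_nh3 = 1e6, ...)
}

# explicit Euler on the full chemical network, written independently of
# the package's solver path (it calls only the public rate/derivative
# API one step at a time)
euler_batch <- function(state0, params, gas = NULL, t_end, dt,
                        aerated = TRUE) {
  y <- c(TAN = state0$TAN, TNN = state0$TNN, NO3_N = state0$NO3_N,
         NO_aq = state0$NO_aq, NO2g_aq = state0$NO2g_aq,
         N2_cum = state0$N2_cum)
  nstep <- round(t_end / dt)
  for (i in seq_len(nstep)) {
    st <- solution_state(TAN = y[["TAN"]], TNN = y[["TNN"]],
                         NO3_N = y[["NO3_N"]], NO_aq = y[["NO_aq"]],
                         NO2g_aq = y[["NO2g_aq"]], N2_cum = y[["N2_cum"]],
                         DO = state0$DO, pH = state0$pH,
                         temperature = state0$temperature,
                         ionic_strength = state0$ionic_strength)
    d <- species_derivatives(st, params, gas, aerated)
    y <- pmax(y + dt * d[names(y)], 0)
  }
  y
}

short_scenario <- function(seed, duration = 4, dt = 0.02, ...) {
  scenario_config(duration = duration, dt = dt, seed = seed, ...)
}
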