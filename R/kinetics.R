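# Chemical nitrite oxidation network at acidic pH:
#   (2) 2 HNO2        <-> NO + NO2 + H2O     (disproportionation)
#   (3) 2 NO + O2      -> 2 NO2              (nitric oxide oxidation)
#   (4) 2 NO2 + H2O   <-> HNO2 + NO3- + H+   (nitrogen dioxide hydrolysis)
#   (5) N2O3           -> NO + NO2           (decomposition)
#   (6) N2O3 + NH3     -> N2 + HNO2 + H2O    (ammonia branch)
# The nitrite/nitrous-acid equilibrium (reaction 1) is instantaneous and
# handled by the speciation layer; N2O3 is a quasi-steady intermediate
# formed from NO + NO2 and partitioned between (5) and (6).

MG_N_PER_MOL <- 14006.7   # mg-N per mol N
MG_O2_PER_MOL <- 31998.8  # mg-O2 per mol O2

#' Solution state of the reactor liquid
#'
#' Concentrations of all dissolved nitrogen pools plus the exogenous
#' conditions (DO, pH, temperature, ionic strength) at one instant. Free
#' NH3 and HNO2 are never stored: they are derived from `TAN`/`TNN` and
#' pH by the speciation layer.
#'
#' @param TAN total ammoniacal nitrogen, mg-N/L.
#' @param TNN total nitrite nitrogen, mg-N/L.
#' @param NO3_N nitrate nitrogen, mg-N/L.
#' @param NO_aq dissolved nitric oxide, mg-N/L.
#' @param NO2g_aq dissolved nitrogen dioxide, mg-N/L.
#' @param N2_cum cumulative dinitrogen produced (bookkeeping), mg-N/L.
#' @param DO dissolved oxygen, mg-O2/L.
#' @param pH reactor pH.
#' @param temperature degrees Celsius.
#' @param ionic_strength mol/L.
#' @return An object of class `solution_state` (named list).
#' @export
solution_state <- function(TAN = 0, TNN = 0, NO3_N = 0, NO_aq = 0,
                           NO2g_aq = 0, N2_cum = 0, DO = 5, pH = 5,
                           temperature = 25, ionic_strength = 0) {
  conc <- c(TAN = TAN, TNN = TNN, NO3_N = NO3_N, NO_aq = NO_aq,
            NO2g_aq = NO2g_aq, N2_cum = N2_cum, DO = DO)
  if (any(conc < 0)) {
    stop("concentrations must be non-negative; got negative ",
         paste(names(conc)[conc < 0], collapse = ", "), call. = FALSE)
  }
  if (pH <= 0 || pH >= 14) stop("'pH' must lie in (0, 14)", call. = FALSE)
  if (ionic_strength < 0) stop("'ionic_strength' must be >= 0", call. = FALSE)
  structure(list(TAN = TAN, TNN = TNN, NO3_N = NO3_N, NO_aq = NO_aq,
                 NO2g_aq = NO2g_aq, N2_cum = N2_cum, DO = DO, pH = pH,
                 temperature = temperature,
                 ionic_strength = ionic_strength),
            class = "solution_state")
}

#' Rate and equilibrium constants of the chemical network
#'
#' All kinetic constants are mass-action constants on the molar scale
#' with time in days. The shipped defaults are order-of-magnitude values
#' assembled from the aqueous nitrogen-oxide literature and are
#' placeholders: verify against the primary kinetic literature before
#' quantitative use. Every constant is configurable and carries a units
#' string in the `units` attribute.
#'
#' @param k_hno2_disp forward constant of the HNO2 disproportionation,
#'   L/(mol d).
#' @param k_no_no2_recomb reverse constant (NO + NO2 + H2O -> 2 HNO2),
#'   L^2/(mol^2 d).
#' @param k_no_oxidation third-order constant of 2NO + O2 -> 2NO2,
#'   L^2/(mol^2 d).
#' @param k_no2_hydrolysis forward constant of the NO2 hydrolysis,
#'   L/(mol d).
#' @param k_no3_recomb reverse constant of the hydrolysis
#'   (HNO2 + NO3- + H+ -> 2 NO2), L^2/(mol^2 d); 0 disables the reverse
#'   path (hydrolysis essentially irreversible above pH 2).
#' @param k_n2o3_formation effective formation constant of N2O3 from
#'   NO + NO2, L/(mol d).
#' @param k_n2o3_decomp first-order decomposition constant of N2O3, 1/d.
#' @param k_n2o3_nh3 second-order constant of the N2O3 + NH3 branch,
#'   L/(mol d).
#' @param nh3_branch logical; `FALSE` disables the ammonia branch
#'   entirely (reactions 5/6 then cancel and the pathway is inert).
#' @param theta common Arrhenius-type temperature correction applied to
#'   all kinetic constants as `k * theta^(T - 25)`; 1 = no correction.
#' @return An object of class `chem_kinetics_params`.
#' @export
chem_kinetics_params <- function(k_hno2_disp = 1.16e6,
                                 k_no_no2_recomb = 1.38e13,
                                 k_no_oxidation = 1.81e11,
                                 k_no2_hydrolysis = 5.6e12,
                                 k_no3_recomb = 0,
                                 k_n2o3_formation = 9.5e13,
                                 k_n2o3_decomp = 7.0e9,
                                 k_n2o3_nh3 = 8.6e12,
                                 nh3_branch = TRUE,
                                 theta = 1) {
  ks <- c(k_hno2_disp = k_hno2_disp, k_no_no2_recomb = k_no_no2_recomb,
          k_no_oxidation = k_no_oxidation,
          k_no2_hydrolysis = k_no2_hydrolysis, k_no3_recomb = k_no3_recomb,
          k_n2o3_formation = k_n2o3_formation,
          k_n2o3_decomp = k_n2o3_decomp, k_n2o3_nh3 = k_n2o3_nh3)
  if (any(ks < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  out <- c(as.list(ks), list(nh3_branch = isTRUE(nh3_branch), theta = theta))
  attr(out, "units") <- c(
    k_hno2_disp = "L mol-1 d-1", k_no_no2_recomb = "L2 mol-2 d-1",
    k_no_oxidation = "L2 mol-2 d-1", k_no2_hydrolysis = "L mol-1 d-1",
    k_no3_recomb = "L2 mol-2 d-1", k_n2o3_formation = "L mol-1 d-1",
    k_n2o3_decomp = "d-1", k_n2o3_nh3 = "L mol-1 d-1",
    theta = "(dimensionless, per degC)")
  class(out) <- "chem_kinetics_params"
  out
}

#' Gas-liquid transfer parameters for volatile nitrogen oxides
#'
#' First-order stripping with zero gas-phase backpressure:
#' `flux_i = kLa_i * C_i`. When the aerator is off the fluxes are scaled
#' by `aeration_off_factor` (residual surface transfer).
#'
#' @param kLa_NO volumetric transfer coefficient for NO, 1/d.
#' @param kLa_NO2 volumetric transfer coefficient for NO2, 1/d.
#' @param aeration_off_factor multiplier in \[0, 1\] applied when not
#'   aerated.
#' @return An object of class `gas_transfer_params`.
#' @export
gas_transfer_params <- function(kLa_NO = 100, kLa_NO2 = 50,
                                aeration_off_factor = 0.1) {
  if (kLa_NO < 0 || kLa_NO2 < 0) stop("kLa must be >= 0", call. = FALSE)
  if (aeration_off_factor < 0 || aeration_off_factor > 1) {
    stop("'aeration_off_factor' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kLa_NO = kLa_NO, kLa_NO2 = kLa_NO2,
                 aeration_off_factor = aeration_off_factor),
            class = "gas_transfer_params")
}

# molar (mol/L) concentrations of the kinetically active species;
# scalar-arithmetic fast path shared by both integrators
.molar_fast <- function(TAN, TNN, NO, NO2, NO3, DO, pH, temp, I, consts) {
  TK <- temp + 273.15
  gamma1 <- if (I > 0) {
    sqI <- sqrt(I)
    10^(-consts$davies_A * (sqI / (1 + sqI) - consts$davies_linear * I))
  } else 1
  pKa_a <- consts$pKa_NH4_coeffs[1] + consts$pKa_NH4_coeffs[2] / TK
  pKa_n <- consts$pKa_HNO2_coeffs[1] + consts$pKa_HNO2_coeffs[2] / TK
  r <- 10^(pH - pKa_a) * gamma1          # [NH3]/[NH4+]
  ratio <- 10^(pH - pKa_n) / gamma1      # [NO2-]/[HNO2]
  list(HNO2 = TNN / (1 + ratio) / MG_N_PER_MOL,
       NH3 = TAN * r / (1 + r) / MG_N_PER_MOL,
       NO = NO / MG_N_PER_MOL,
       NO2 = NO2 / MG_N_PER_MOL,
       NO3 = NO3 / MG_N_PER_MOL,
       O2 = DO / MG_O2_PER_MOL,
       H = 10^(-pH))
}

.molar_species <- function(state, consts = speciation_constants()) {
  .molar_fast(state$TAN, state$TNN, state$NO_aq, state$NO2g_aq,
              state$NO3_N, state$DO, state$pH, state$temperature,
              state$ionic_strength, consts)
}

# event rates (mol/(L d)) from molar concentrations
.rates_fast <- function(m, params, temp) {
  tcorr <- if (params$theta == 1) 1 else params$theta^(temp - 25)
  r2f <- params$k_hno2_disp * tcorr * m$HNO2^2
  r2r <- params$k_no_no2_recomb * tcorr * m$NO * m$NO2
  r3 <- params$k_no_oxidation * tcorr * m$NO^2 * m$O2
  r4f <- params$k_no2_hydrolysis * tcorr * m$NO2^2
  r4r <- params$k_no3_recomb * tcorr * m$HNO2 * m$NO3 * m$H
  phi <- if (params$nh3_branch && m$NH3 > 0) {
    kn <- params$k_n2o3_nh3 * tcorr * m$NH3
    kn / (params$k_n2o3_decomp * tcorr + kn)
  } else 0
  r56 <- params$k_n2o3_formation * tcorr * m$NO * m$NO2 * phi
  list(r2f = r2f, r2r = r2r, r3 = r3, r4f = r4f, r4r = r4r, r56 = r56)
}

# partial derivatives of the event rates w.r.t. the five liquid pools
# (mg-N basis); used to assemble analytic Jacobians for the stiff solver
.chem_jac_parts <- function(TAN, TNN, NO3, NO, NO2, DO, pH, temp, I,
                            params, consts) {
  m <- .molar_fast(TAN, TNN, NO, NO2, NO3, DO, pH, temp, I, consts)
  u <- 1 / MG_N_PER_MOL
  fa_hno2 <- if (TNN > 0) m$HNO2 / (TNN * u) else {
    mm <- .molar_fast(TAN, 1, NO, NO2, NO3, DO, pH, temp, I, consts)
    mm$HNO2 / u
  }
  fa_nh3 <- if (TAN > 0) m$NH3 / (TAN * u) else {
    mm <- .molar_fast(1, TNN, NO, NO2, NO3, DO, pH, temp, I, consts)
    mm$NH3 / u
  }
  tcorr <- if (params$theta == 1) 1 else params$theta^(temp - 25)
  A2 <- 2 * params$k_hno2_disp * tcorr * m$HNO2 * fa_hno2 * u
  B4 <- params$k_no_no2_recomb * tcorr * m$NO2 * u
  B5 <- params$k_no_no2_recomb * tcorr * m$NO * u
  C4 <- 2 * params$k_no_oxidation * tcorr * m$NO * m$O2 * u
  D5 <- 2 * params$k_no2_hydrolysis * tcorr * m$NO2 * u
  E2 <- params$k_no3_recomb * tcorr * fa_hno2 * u * m$NO3 * m$H
  E3 <- params$k_no3_recomb * tcorr * m$HNO2 * m$H * u
  if (params$nh3_branch) {
    kn <- params$k_n2o3_nh3 * tcorr
    kd <- params$k_n2o3_decomp * tcorr
    phi <- kn * m$NH3 / (kd + kn * m$NH3)
    dphi <- kn * kd / (kd + kn * m$NH3)^2 * fa_nh3 * u
  } else {
    phi <- 0; dphi <- 0
  }
  kf <- params$k_n2o3_formation * tcorr
  G1 <- kf * m$NO * m$NO2 * dphi
  G4 <- kf * m$NO2 * phi * u
  G5 <- kf * m$NO * phi * u
  list(A2 = A2, B4 = B4, B5 = B5, C4 = C4, D5 = D5, E2 = E2, E3 = E3,
       G1 = G1, G4 = G4, G5 = G5)
}

# 5x5 Jacobian of the chemical terms (mg-N/(L d) per mg-N/L), plus the
# N2 row gradient; stripping constants enter the NO/NO2 diagonal
.chem_jac_fast <- function(TAN, TNN, NO3, NO, NO2, DO, pH, temp, I,
                           params, consts, kLa_NO = 0, kLa_NO2 = 0) {
  p <- .chem_jac_parts(TAN, TNN, NO3, NO, NO2, DO, pH, temp, I,
                       params, consts)
  M <- MG_N_PER_MOL
  J <- matrix(0, 6, 5,
              dimnames = list(c("TAN", "TNN", "NO3_N", "NO_aq",
                                "NO2g_aq", "N2_cum"), NULL))
  J[1, ] <- c(-M * p$G1, 0, 0, -M * p$G4, -M * p$G5)
  J[2, ] <- c(M * p$G1, -2 * M * p$A2 - M * p$E2, -M * p$E3,
              M * (2 * p$B4 + p$G4), M * (2 * p$B5 + p$D5 + p$G5))
  J[3, ] <- c(0, -M * p$E2, -M * p$E3, 0, M * p$D5)
  J[4, ] <- c(-M * p$G1, M * p$A2, 0,
              -M * (p$B4 + 2 * p$C4 + p$G4) - kLa_NO,
              -M * (p$B5 + p$G5))
  J[5, ] <- c(-M * p$G1, M * (p$A2 + 2 * p$E2), 2 * M * p$E3,
              M * (-p$B4 + 2 * p$C4 - p$G4),
              -M * (p$B5 + 2 * p$D5 + p$G5) - kLa_NO2)
  J[6, ] <- c(2 * M * p$G1, 0, 0, 2 * M * p$G4, 2 * M * p$G5)
  J
}

# derivatives (mg-N/(L d)) + stripping fluxes; y = c(TAN, TNN, NO3, NO, NO2)
.chem_derivs_fast <- function(TAN, TNN, NO3, NO, NO2, DO, pH, temp, I,
                              params, consts, kLa_NO = 0, kLa_NO2 = 0) {
  m <- .molar_fast(TAN, TNN, NO, NO2, NO3, DO, pH, temp, I, consts)
  r <- .rates_fast(m, params, temp)
  n2 <- r$r2f - r$r2r
  n4 <- r$r4f - r$r4r
  sNO <- kLa_NO * NO
  sNO2 <- kLa_NO2 * NO2
  c(TAN = -r$r56 * MG_N_PER_MOL,
    TNN = (-2 * n2 + n4 + r$r56) * MG_N_PER_MOL,
    NO3_N = n4 * MG_N_PER_MOL,
    NO_aq = (n2 - 2 * r$r3 - r$r56) * MG_N_PER_MOL - sNO,
    NO2g_aq = (n2 + 2 * r$r3 - 2 * n4 - r$r56) * MG_N_PER_MOL - sNO2,
    N2_cum = 2 * r$r56 * MG_N_PER_MOL,
    strip_NO = sNO, strip_NO2 = sNO2)
}

#' Reaction rates of the chemical network
#'
#' Evaluates the mass-action rate of every reaction at the given state.
#' Rates are reaction-event rates in mol/(L d); forward and reverse
#' components of the reversible steps are reported separately together
#' with the net rates. The ammonia-branch rate uses the quasi-steady
#' N2O3 partitioning `phi = k_nh3 [NH3] / (k_dec + k_nh3 [NH3])`.
#'
#' @param state a [solution_state()].
#' @param params a [chem_kinetics_params()].
#' @param consts a [speciation_constants()] object.
#' @return A named list of class `rate_vector`: `r_hno2_disp_fwd`,
#'   `r_hno2_disp_rev`, `r_hno2_disp` (net), `r_no_oxidation`,
#'   `r_no2_hydrolysis_fwd`, `r_no2_hydrolysis_rev`, `r_no2_hydrolysis`
#'   (net), `r_n2o3_nh3`, all in mol/(L d).
#' @export
reaction_rates <- function(state, params = chem_kinetics_params(),
                           consts = speciation_constants()) {
  if (!inherits(state, "solution_state")) state <- do.call(solution_state, state)
  m <- .molar_species(state, consts)
  r <- .rates_fast(m, params, state$temperature)
  structure(list(r_hno2_disp_fwd = r$r2f, r_hno2_disp_rev = r$r2r,
                 r_hno2_disp = r$r2f - r$r2r,
                 r_no_oxidation = r$r3,
                 r_no2_hydrolysis_fwd = r$r4f, r_no2_hydrolysis_rev = r$r4r,
                 r_no2_hydrolysis = r$r4f - r$r4r,
                 r_n2o3_nh3 = r$r56),
            class = "rate_vector")
}

#' Gas stripping fluxes
#'
#' First-order loss of dissolved NO and NO2 to the off-gas,
#' `flux_i = kLa_i * C_i`, scaled by `aeration_off_factor` when not
#' aerated.
#'
#' @param state a [solution_state()].
#' @param gas a [gas_transfer_params()].
#' @param aerated logical, aeration on?
#' @return Named vector `c(NO = , NO2 = )` in mg-N/(L d).
#' @export
strip_gas <- function(state, gas = gas_transfer_params(), aerated = TRUE) {
  fac <- if (isTRUE(aerated)) 1 else gas$aeration_off_factor
  c(NO = fac * gas$kLa_NO * state$NO_aq,
    NO2 = fac * gas$kLa_NO2 * state$NO2g_aq)
}

#' Species derivatives of the chemical network
#'
#' Maps the reaction rates onto per-species time derivatives in
#' mg-N/(L d) (DO, pH, temperature are exogenous and carry no
#' derivative). Stoichiometry per reaction event: disproportionation
#' consumes 2 TNN and produces NO + NO2; NO oxidation converts 2 NO to
#' 2 NO2; hydrolysis converts 2 NO2 to TNN + NO3; the ammonia branch
#' consumes NO + NO2 + TAN and produces TNN + 2 N2. Total nitrogen
#' (including the N2 bookkeeping pool) is conserved exactly; stripping,
#' when enabled, removes NO/NO2 from the liquid.
#'
#' @inheritParams reaction_rates
#' @param gas optional [gas_transfer_params()]; `NULL` disables
#'   stripping.
#' @param aerated logical, aeration on (affects stripping only).
#' @return Named numeric of derivatives (mg-N/(L d)) for `TAN`, `TNN`,
#'   `NO3_N`, `NO_aq`, `NO2g_aq`, `N2_cum`, with the stripping fluxes in
#'   the `"stripping"` attribute.
#' @export
species_derivatives <- function(state, params = chem_kinetics_params(),
                                gas = NULL, aerated = TRUE,
                                consts = speciation_constants()) {
  r <- reaction_rates(state, params, consts)
  n2 <- r$r_hno2_disp      # net disproportionation
  n3 <- r$r_no_oxidation
  n4 <- r$r_no2_hydrolysis # net hydrolysis
  n56 <- r$r_n2o3_nh3
  d <- c(
    TAN = -n56,
    TNN = -2 * n2 + n4 + n56,
    NO3_N = n4,
    NO_aq = n2 - 2 * n3 - n56,
    NO2g_aq = n2 + 2 * n3 - 2 * n4 - n56,
    N2_cum = 2 * n56
  ) * MG_N_PER_MOL
  strip <- c(NO = 0, NO2 = 0)
  if (!is.null(gas)) {
    strip <- strip_gas(state, gas, aerated)
    d["NO_aq"] <- d["NO_aq"] - strip[["NO"]]
    d["NO2g_aq"] <- d["NO2g_aq"] - strip[["NO2"]]
  }
  attr(d, "stripping") <- strip
  d
}

#' Integrate the chemical network in a closed (batch) system
#'
#' Stiff-capable adaptive integration (deSolve, `lsoda`) of the reaction
#' network at fixed pH, DO, temperature and ionic strength. Cumulative
#' stripped NO and NO2 are tracked as auxiliary states so the nitrogen
#' balance can be closed exactly. Sub-tolerance negative excursions are
#' clipped to zero with a warning.
#'
#' @param state0 initial [solution_state()].
#' @param params a [chem_kinetics_params()].
#' @param gas optional [gas_transfer_params()] (`NULL` = no stripping).
#' @param t_end horizon in days.
#' @param dt_out output step in days (default `t_end/100`).
#' @param aerated logical, aeration on.
#' @param rtol,atol integration tolerances (mg-N/L for `atol`).
#' @param consts a [speciation_constants()] object.
#' @return A `data.frame` (class `batch_trajectory`) with columns
#'   `time`, the six nitrogen pools, and cumulative `strip_NO`,
#'   `strip_NO2` (mg-N/L equivalents). Solver diagnostics are attached
#'   as the `"diagnostics"` attribute.
#' @export
integrate_batch <- function(state0, params = chem_kinetics_params(),
                            gas = NULL, t_end, dt_out = t_end / 100,
                            aerated = TRUE, rtol = 1e-6, atol = 1e-9,
                            consts = speciation_constants()) {
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (!inherits(state0, "solution_state")) {
    state0 <- do.call(solution_state, state0)
  }
  y0 <- c(TAN = state0$TAN, TNN = state0$TNN, NO3_N = state0$NO3_N,
          NO_aq = state0$NO_aq, NO2g_aq = state0$NO2g_aq,
          N2_cum = state0$N2_cum, strip_NO = 0, strip_NO2 = 0)
  env <- list(pH = state0$pH, DO = state0$DO,
              temperature = state0$temperature,
              ionic_strength = state0$ionic_strength)
  fac <- if (isTRUE(aerated) || is.null(gas)) 1 else gas$aeration_off_factor
  kNO <- if (is.null(gas)) 0 else fac * gas$kLa_NO
  kNO2 <- if (is.null(gas)) 0 else fac * gas$kLa_NO2
  deriv <- function(t, y, p) {
    y[y < 0] <- 0
    d <- .chem_derivs_fast(y[1L], y[2L], y[3L], y[4L], y[5L],
                           env$DO, env$pH, env$temperature,
                           env$ionic_strength, params, consts, kNO, kNO2)
    list(d)
  }
  jac <- function(t, y, p) {
    y[y < 0] <- 0
    Jc <- .chem_jac_fast(y[1L], y[2L], y[3L], y[4L], y[5L],
                         env$DO, env$pH, env$temperature,
                         env$ionic_strength, params, consts, kNO, kNO2)
    J <- matrix(0, 8, 8)
    J[1:6, 1:5] <- Jc
    J[7, 4] <- kNO
    J[8, 5] <- kNO2
    J
  }
  times <- unique(c(seq(0, t_end, by = dt_out), t_end))
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integrator failed at t = ",
         signif(max(sol[, "time"]), 6),
         " d; last state: ",
         paste(sprintf("%s=%.4g", colnames(sol)[-1],
                       sol[nrow(sol), -1]), collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(unclass(sol))
  neg <- out < 0
  if (any(neg)) {
    if (min(out[neg]) < -atol * 10) {
      warning("negative excursions beyond tolerance clipped to zero",
              call. = FALSE)
    }
    out[neg] <- 0
  }
  attr(out, "diagnostics") <- list(istate = attr(sol, "istate"),
                                   rstate = attr(sol, "rstate"))
  attr(out, "conditions") <- env
  class(out) <- c("batch_trajectory", "data.frame")
  out
}

#' Total nitrogen of a trajectory row or state
#'
#' Sum of all nitrogen pools (liquid + N2 bookkeeping + cumulative
#' stripped, when present), in mg-N/L equivalents.
#'
#' @param x a `solution_state`, `batch_trajectory` or data.frame with
#'   the nitrogen pool columns.
#' @return Numeric vector of total nitrogen.
#' @export
total_nitrogen <- function(x) {
  if (inherits(x, "solution_state")) {
    return(x$TAN + x$TNN + x$NO3_N + x$NO_aq + x$NO2g_aq + x$N2_cum)
  }
  tot <- x$TAN + x$TNN + x$NO3_N + x$NO_aq + x$NO2g_aq + x$N2_cum
  if (!is.null(x$strip_NO)) tot <- tot + x$strip_NO + x$strip_NO2
  tot
}
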