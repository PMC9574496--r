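test_that("empty system has zero rates; oxygen gates NO oxidation", {
  st0 <- solution_state(TAN = 100, TNN = 0, NO_aq = 0, NO2g_aq = 0, pH = 5)
  r0 <- reaction_rates(st0)
  expect_true(all(abs(unlist(unclass(r0))) == 0))
  st <- solution_state(TNN = 300, NO_aq = 5, NO2g_aq = 0, DO = 0, pH = 5)
  expect_identical(reaction_rates(st)$r_no_oxidation, 0)
  expect_error(solution_state(TNN = -1), "non-negative")
})

test_that("mass-action orders hold under doubling", {
  base <- solution_state(TAN = 500, TNN = 200, NO3_N = 50, NO_aq = 0.4,
                         NO2g_aq = 0.2, DO = 5, pH = 5)
  p <- mild_kinetics()
  r <- reaction_rates(base, p)
  # HNO2 doubles with TNN at fixed pH -> forward disproportionation x4
  r2 <- reaction_rates(modifyList(base, list(TNN = 400)), p)
  expect_equal(r2$r_hno2_disp_fwd / r$r_hno2_disp_fwd, 4, tolerance = 1e-9)
  # NO doubling: recombination x2, NO oxidation x4
  rNO <- reaction_rates(modifyList(base, list(NO_aq = 0.8)), p)
  expect_equal(rNO$r_hno2_disp_rev / r$r_hno2_disp_rev, 2, tolerance = 1e-9)
  expect_equal(rNO$r_no_oxidation / r$r_no_oxidation, 4, tolerance = 1e-9)
  # DO doubling: NO oxidation x2
  rDO <- reaction_rates(modifyList(base, list(DO = 10)), p)
  expect_equal(rDO$r_no_oxidation / r$r_no_oxidation, 2, tolerance = 1e-9)
  # NO2 doubling: hydrolysis x4
  rNO2 <- reaction_rates(modifyList(base, list(NO2g_aq = 0.4)), p)
  expect_equal(rNO2$r_no2_hydrolysis_fwd / r$r_no2_hydrolysis_fwd, 4,
               tolerance = 1e-9)
  # reverse hydrolysis is first order in each of HNO2, NO3 and H+
  rrev <- reaction_rates(modifyList(base, list(NO3_N = 100)), p)
  expect_equal(rrev$r_no2_hydrolysis_rev / r$r_no2_hydrolysis_rev, 2,
               tolerance = 1e-9)
})

test_that("derivatives conserve nitrogen and map stoichiometry correctly", {
  st <- solution_state(TAN = 900, TNN = 400, NO3_N = 80, NO_aq = 1,
                       NO2g_aq = 0.5, DO = 5, pH = 4.8)
  d <- species_derivatives(st, mild_kinetics())
  expect_lt(abs(sum(d)), 1e-8 * sum(abs(d)))
  # zero state -> zero derivatives
  d0 <- species_derivatives(solution_state(pH = 5), mild_kinetics())
  expect_true(all(d0 == 0))
  # NO2 pulse with only hydrolysis active: dNO3 = dTNN at every instant
  p4 <- chem_kinetics_params(0, 0, 0, 1e5, 0, 0, 1, 0)
  dp <- species_derivatives(solution_state(NO2g_aq = 10, pH = 5), p4)
  expect_equal(dp[["NO3_N"]], dp[["TNN"]], tolerance = 1e-12)
  expect_equal(dp[["NO2g_aq"]], -2 * dp[["NO3_N"]], tolerance = 1e-12)
})

test_that("stripping is first order with an aeration-off multiplier", {
  st <- solution_state(NO_aq = 2, NO2g_aq = 1, pH = 5)
  g <- gas_transfer_params(kLa_NO = 30, kLa_NO2 = 10,
                           aeration_off_factor = 0.1)
  f <- strip_gas(st, g)
  expect_equal(unname(f), c(60, 10))
  st2 <- solution_state(NO_aq = 4, NO2g_aq = 2, pH = 5)
  expect_equal(unname(strip_gas(st2, g)), 2 * unname(f))
  expect_equal(unname(strip_gas(st, g, aerated = FALSE)), 0.1 * unname(f))
  expect_equal(unname(strip_gas(st, gas_transfer_params(0, 0))), c(0, 0))
  expect_error(gas_transfer_params(aeration_off_factor = 2), "aeration_off")
})

test_that("closed-system integration conserves nitrogen to 1e-6 relative", {
  st <- solution_state(TAN = 1500, TNN = 600, NO3_N = 100, NO_aq = 0.5,
                       NO2g_aq = 0.2, DO = 5, pH = 4.9,
                       ionic_strength = 0.4)
  for (p in list(mild_kinetics(), chem_kinetics_params())) {
    tr <- integrate_batch(st, p, gas = NULL, t_end = 1)
    tot <- total_nitrogen(tr)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
    expect_true(all(as.matrix(tr) >= 0))
  }
})

test_that("all-zero kinetics freeze the state", {
  p0 <- chem_kinetics_params(0, 0, 0, 0, 0, 0, 1, 0)
  st <- solution_state(TAN = 100, TNN = 50, NO3_N = 10, pH = 5)
  tr <- integrate_batch(st, p0, t_end = 2)
  expect_equal(tr$TAN, rep(100, nrow(tr)), tolerance = 1e-10)
  expect_equal(tr$TNN, rep(50, nrow(tr)), tolerance = 1e-10)
  expect_error(integrate_batch(st, p0, t_end = -1), "t_end")
})

test_that("stiff solver agrees with a fixed-step explicit-Euler oracle", {
  st <- solution_state(TAN = 800, TNN = 300, NO3_N = 20, NO_aq = 0.3,
                       NO2g_aq = 0.1, DO = 5, pH = 4.8)
  p <- mild_kinetics()
  g <- gas_transfer_params(kLa_NO = 40, kLa_NO2 = 20)
  oracle <- euler_batch(st, p, g, t_end = 0.01, dt = 1e-5)
  tr <- integrate_batch(st, p, g, t_end = 0.01, dt_out = 0.01)
  got <- unlist(tr[nrow(tr), c("TAN", "TNN", "NO3_N", "NO_aq",
                               "NO2g_aq", "N2_cum")])
  for (nm in names(oracle)) {
    expect_equal(got[[nm]], oracle[[nm]], tolerance = 1e-3)
  }
})

test_that("detailed balance: reversible reactions at equilibrium have zero net rate", {
  st <- solution_state(TAN = 0, TNN = 100, NO3_N = 50, NO_aq = 1,
                       NO2g_aq = 2, DO = 5, pH = 5)
  m <- nitroxsim:::.molar_species(st, speciation_constants())
  k2f <- 1e4
  k2r <- k2f * m$HNO2^2 / (m$NO * m$NO2)
  k4f <- 1e4
  k4r <- k4f * m$NO2^2 / (m$HNO2 * m$NO3 * m$H)
  p <- chem_kinetics_params(k_hno2_disp = k2f, k_no_no2_recomb = k2r,
                            k_no_oxidation = 0, k_no2_hydrolysis = k4f,
                            k_no3_recomb = k4r, k_n2o3_formation = 0,
                            k_n2o3_decomp = 1, k_n2o3_nh3 = 0,
                            nh3_branch = FALSE)
  r <- reaction_rates(st, p)
  expect_equal(r$r_hno2_disp, 0, tolerance = 1e-9 * r$r_hno2_disp_fwd)
  expect_equal(r$r_no2_hydrolysis, 0,
               tolerance = 1e-9 * r$r_no2_hydrolysis_fwd)
  expect_true(all(abs(species_derivatives(st, p)) < 1e-6))
})

test_that("analytic Jacobian matches a central-difference Jacobian", {
  chem <- chem_kinetics_params()
  sc <- speciation_constants()
  y <- c(800, 400, 120, 0.03, 0.002)
  f <- function(y) {
    nitroxsim:::.chem_derivs_fast(y[1], y[2], y[3], y[4], y[5],
                                  5, 5, 25, 0.45, chem, sc, 100, 50)[1:6]
  }
  Jn <- sapply(1:5, function(j) {
    h <- max(1e-7 * abs(y[j]), 1e-10)
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    (f(yp) - f(ym)) / (2 * h)
  })
  Ja <- nitroxsim:::.chem_jac_fast(y[1], y[2], y[3], y[4], y[5],
                                   5, 5, 25, 0.45, chem, sc, 100, 50)
  expect_lt(max(abs(Ja - Jn) / (abs(Jn) + 1e-6)), 1e-5)
})

test_that("kinetics YAML config round-trips exactly", {
  p <- chem_kinetics_params(k_no3_recomb = 12.5, theta = 1.07,
                            nh3_branch = FALSE)
  g <- gas_transfer_params(kLa_NO = 80, kLa_NO2 = 25)
  f <- tempfile(fileext = ".yaml")
  write_kinetics_config(p, f, gas = g)
  back <- read_kinetics_config(f)
  expect_equal(back$chem, p)
  expect_equal(back$gas, g)
  # schema violations fail loudly
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(constants = list(k_hno2_disp = 1)), bad)
  expect_error(read_kinetics_config(bad), "missing constants")
})
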