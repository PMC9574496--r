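no_chem <- chem_kinetics_params(0, 0, 0, 0, 0, 0, 1, 0)

const_timeline <- function(duration = 20, dt = 0.1, Q = 6, TAN_in = 2000,
                           pH = 5, f_ox = 0, volume = 12) {
  operation_timeline(time = seq(0, duration, by = dt), Q = Q,
                     TAN_in = TAN_in, pH = pH, DO = 5, temperature = 25,
                     conductivity = 30, volume = volume, f_ox = f_ox)
}

test_that("timeline validation rejects malformed drivers", {
  expect_error(operation_timeline(c(0, 1, 1), 1, 100, 5), "strictly")
  expect_error(const_timeline(f_ox = 1.5), "f_ox")
  expect_error(operation_timeline(0:2, -1, 100, 5), "Q")
  expect_error(operation_timeline(0:2, 1, 100, 5, volume = 0), "volume")
})

test_that("imposed nitrite source follows the influent load", {
  tl <- const_timeline(Q = 6, TAN_in = 2000, f_ox = 0.5, volume = 12)
  # load Q*TAN_in/V = 1000 mg-N/(L d); half of it becomes nitrite
  expect_equal(nitrite_source_rate(tl, 5), 500)
  tl0 <- const_timeline(f_ox = 0)
  expect_equal(nitrite_source_rate(tl0, 5), 0)
  tl1 <- const_timeline(f_ox = 1)
  expect_equal(nitrite_source_rate(tl1, 5), 1000)
})

test_that("no source and no chemistry yield no nitrate", {
  tl <- const_timeline(duration = 5, f_ox = 0)
  res <- simulate_reactor(tl, chem = no_chem, gas = NULL)
  expect_true(all(res$series$NO3_N == 0))
  expect_true(all(res$series$TNN == 0))
})

test_that("inert tracer matches the analytic CSTR washout curve", {
  tl <- const_timeline(duration = 12, dt = 0.05, Q = 6, TAN_in = 2000,
                       f_ox = 0)  # HRT = 2 d -> 12 d = 6 HRT
  res <- simulate_reactor(tl, chem = no_chem, gas = NULL)
  D <- 6 / 12
  analytic <- 2000 * (1 - exp(-res$series$time * D))
  after5 <- res$series$time >= 10
  relerr <- abs(res$series$TAN[after5] - analytic[after5]) /
    analytic[after5]
  expect_lt(max(relerr), 1e-3)
})

test_that("whole-run nitrogen balance closes for a driven run", {
  tl <- const_timeline(duration = 6, dt = 0.05, f_ox = 0.5)
  res <- simulate_reactor(tl)
  expect_lt(res$balance$relative_error, 1e-4)
  # cumulative quantities are non-decreasing by construction
  expect_true(res$cumulative$influent_N >= 0)
  expect_true(res$cumulative$stripped_NO >= 0)
  expect_true(res$cumulative$N2 >= 0)
})

test_that("lower driven pH never decreases chemical nitrate or gas loss", {
  base <- function(ph) {
    tl <- const_timeline(duration = 4, dt = 0.05, f_ox = 0.5, pH = ph)
    simulate_reactor(tl)
  }
  phs <- c(5.6, 5.2, 4.8, 4.4)
  runs <- lapply(phs, base)
  no3 <- vapply(runs, function(r) r$series$NO3_N[nrow(r$series)],
                numeric(1))
  gas <- vapply(runs, function(r)
    r$cumulative$stripped_NO + r$cumulative$stripped_NO2 +
      r$cumulative$N2, numeric(1))
  expect_true(all(diff(no3) >= -1e-9 * max(no3)))
  expect_true(all(diff(gas) >= -1e-9 * max(gas)))
})

test_that("simulation is deterministic for identical inputs", {
  tl <- const_timeline(duration = 3, dt = 0.05, f_ox = 0.5)
  r1 <- simulate_reactor(tl)
  r2 <- simulate_reactor(tl)
  expect_identical(r1$series, r2$series)
})

test_that("fit report reproduces the known efficiency cases", {
  tl <- const_timeline(duration = 2, dt = 0.5, f_ox = 0.5)
  res <- simulate_reactor(tl)
  perfect <- fit_to_measurements(res, res$series$TNN, res$series$NO3_N)
  expect_equal(perfect$E_TNN, 1)
  expect_equal(perfect$E_NO3, 1)
  mean_pred <- res$series$TNN * 0 + 1  # constant measured series errors
  expect_error(fit_to_measurements(res, mean_pred, res$series$NO3_N),
               "constant")
  # misaligned vector lengths are rejected
  expect_error(fit_to_measurements(res, res$series$TNN[-1],
                                   res$series$NO3_N), "length")
  # measured series on its own grid is interpolated (with a message)
  m <- data.frame(time = c(0.25, 0.75, 1.2, 1.9),
                  value = c(10, 20, 35, 42))
  expect_message(
    fr <- fit_to_measurements(res, m, m),
    "interpolated")
  expect_true(fr$E_TNN <= 1)
})

test_that("timeline CSV round-trips including the reactor volume", {
  tl <- const_timeline(duration = 1, dt = 0.25, volume = 8)
  f <- tempfile(fileext = ".csv")
  write_timeline_csv(tl, f)
  back <- read_timeline_csv(f)
  expect_equal(attr(back, "volume"), 8)
  expect_equal(back$time, tl$time)
  expect_equal(back$TAN_in, tl$TAN_in)
  expect_equal(back$f_ox, tl$f_ox)
})
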