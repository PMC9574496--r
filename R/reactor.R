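# Driven CSTR simulation: measured flow, influent TAN, imposed
# ammonia-to-nitrite conversion and measured pH/DO/T as exogenous inputs;
# the chemistry supplies the abiotic nitrite-oxidation source terms.
# Biology is deliberately absent: the model answers how much nitrate the
# chemistry alone can explain.

#' Reactor operation timeline
#'
#' Exogenous drivers of the reactor on a strictly increasing time grid,
#' plus the (constant) reactor volume and the imposed fraction of
#' influent TAN oxidized to nitrite.
#'
#' @param time time grid in days, strictly increasing.
#' @param Q influent flow, L/d (vector or scalar).
#' @param TAN_in influent total ammoniacal nitrogen, mg-N/L.
#' @param pH reactor pH series.
#' @param DO dissolved oxygen, mg-O2/L.
#' @param temperature degrees Celsius.
#' @param conductivity mS/cm.
#' @param volume reactor volume, L.
#' @param f_ox fraction of the influent TAN load oxidized to nitrite
#'   (scalar or series), in \[0, 1\]. The default 0.5 reflects
#'   alkalinity-limited conversion of urine (see
#'   [alkalinity_limited_fraction()]).
#' @return A `data.frame` of class `operation_timeline` with the volume
#'   in attribute `"volume"`.
#' @export
operation_timeline <- function(time, Q, TAN_in, pH, DO = 5,
                               temperature = 25, conductivity = 30,
                               volume = 12, f_ox = 0.5) {
  time <- as.numeric(time)
  if (length(time) < 2 || any(diff(time) <= 0)) {
    stop("'time' must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  n <- length(time)
  rep_n <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) == 1) x <- rep(x, n)
    if (length(x) != n) {
      stop("'", nm, "' must have length 1 or length(time)", call. = FALSE)
    }
    x
  }
  df <- data.frame(time = time, Q = rep_n(Q, "Q"),
                   TAN_in = rep_n(TAN_in, "TAN_in"), pH = rep_n(pH, "pH"),
                   DO = rep_n(DO, "DO"),
                   temperature = rep_n(temperature, "temperature"),
                   conductivity = rep_n(conductivity, "conductivity"),
                   f_ox = rep_n(f_ox, "f_ox"))
  if (any(df$Q < 0)) stop("'Q' must be >= 0", call. = FALSE)
  if (any(df$f_ox < 0 | df$f_ox > 1)) {
    stop("'f_ox' must lie in [0, 1]", call. = FALSE)
  }
  if (volume <= 0) stop("'volume' must be > 0", call. = FALSE)
  attr(df, "volume") <- volume
  class(df) <- c("operation_timeline", "data.frame")
  df
}

#' Read / write the timeline CSV dialect
#'
#' Columns `time_d, Q_L_per_d, TAN_in_mgN_L, pH, DO_mg_L, T_C, EC_mS_cm`
#' plus optional `f_ox`; header required; decimal point, comma
#' separated. The reactor volume travels in a `# volume_L: <x>` comment
#' on the first line (default 12 L when absent).
#'
#' @param path file path.
#' @param timeline an [operation_timeline()] (for writing).
#' @return `read_timeline_csv()` returns an [operation_timeline()].
#' @export
read_timeline_csv <- function(path) {
  first <- readLines(path, n = 1)
  volume <- 12
  if (grepl("^#\\s*volume_L:", first)) {
    volume <- as.numeric(sub("^#\\s*volume_L:\\s*", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_d", "Q_L_per_d", "TAN_in_mgN_L", "pH", "DO_mg_L",
            "T_C", "EC_mS_cm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("timeline CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  operation_timeline(time = df$time_d, Q = df$Q_L_per_d,
                     TAN_in = df$TAN_in_mgN_L, pH = df$pH, DO = df$DO_mg_L,
                     temperature = df$T_C, conductivity = df$EC_mS_cm,
                     volume = volume,
                     f_ox = if ("f_ox" %in% names(df)) df$f_ox else 0.5)
}

#' @rdname read_timeline_csv
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(inherits(timeline, "operation_timeline"))
  out <- data.frame(time_d = timeline$time, Q_L_per_d = timeline$Q,
                    TAN_in_mgN_L = timeline$TAN_in, pH = timeline$pH,
                    DO_mg_L = timeline$DO, T_C = timeline$temperature,
                    EC_mS_cm = timeline$conductivity, f_ox = timeline$f_ox)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# volume_L: %.10g", attr(timeline, "volume")), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# driver interpolators: zero-order hold for pump/control signals,
# piecewise linear for the slowly varying physico-chemical channels
.timeline_funs <- function(timeline) {
  zoh <- function(v) stats::approxfun(timeline$time, v, method = "constant",
                                      rule = 2, f = 0)
  lin <- function(v) stats::approxfun(timeline$time, v, rule = 2)
  list(Q = zoh(timeline$Q), TAN_in = zoh(timeline$TAN_in),
       f_ox = zoh(timeline$f_ox), pH = lin(timeline$pH),
       DO = lin(timeline$DO), temperature = lin(timeline$temperature),
       conductivity = lin(timeline$conductivity))
}

#' Imposed nitrite source rate
#'
#' The ammonia-to-nitrite conversion is not modeled biologically; the
#' observed conversion is imposed: a fraction `f_ox` of the influent TAN
#' load appears as nitrite, `source = f_ox(t) * Q(t) * TAN_in(t) / V`
#' (mg-N/(L d)). The same nitrogen is removed from the TAN pool.
#'
#' @param timeline an [operation_timeline()].
#' @param t time in days (vectorized).
#' @return Source rate in mg-N/(L d).
#' @export
nitrite_source_rate <- function(timeline, t) {
  stopifnot(inherits(timeline, "operation_timeline"))
  f <- .timeline_funs(timeline)
  V <- attr(timeline, "volume")
  f$f_ox(t) * f$Q(t) * f$TAN_in(t) / V
}

#' Simulate the driven CSTR
#'
#' Integrates, for each dissolved pool,
#' `dC/dt = (Q/V) (C_in - C) + imposed nitrite source/sink + chemical
#' derivatives + stripping`, with pH, DO, temperature and conductivity
#' read from the timeline (never computed). Cumulative influent,
#' effluent, stripped and N2 masses are co-integrated so the whole-run
#' nitrogen balance closes by construction.
#'
#' @param timeline an [operation_timeline()].
#' @param chem a [chem_kinetics_params()].
#' @param gas a [gas_transfer_params()] or `NULL` to disable stripping.
#' @param speciation a [speciation_constants()] object.
#' @param state0 optional initial [solution_state()]; default is
#'   nitrogen-free water at the timeline's initial pH/DO/T.
#' @param times optional output grid (default: the timeline grid).
#' @param rtol,atol integrator tolerances.
#' @param ec_factor conductivity-to-ionic-strength factor, mol/L per
#'   mS/cm.
#' @param maxsteps integrator step budget per output interval.
#' @return An object of class `simulation_result`: list with `series`
#'   (data.frame: time, drivers, species, instantaneous rates),
#'   `cumulative` (influent/effluent/stripped/N2 masses in mg-N),
#'   `balance` (closure diagnostics) and `diagnostics`.
#' @export
simulate_reactor <- function(timeline, chem = chem_kinetics_params(),
                             gas = gas_transfer_params(),
                             speciation = speciation_constants(),
                             state0 = NULL, times = NULL,
                             rtol = 1e-6, atol = 1e-6,
                             ec_factor = 0.016, maxsteps = 100000) {
  stopifnot(inherits(timeline, "operation_timeline"))
  fns <- .timeline_funs(timeline)
  V <- attr(timeline, "volume")
  if (is.null(times)) times <- timeline$time
  t0 <- times[1]

  if (is.null(state0)) {
    state0 <- solution_state(DO = fns$DO(t0), pH = fns$pH(t0),
                             temperature = fns$temperature(t0))
  }
  liquid <- c("TAN", "TNN", "NO3_N", "NO_aq", "NO2g_aq")
  y0 <- c(TAN = state0$TAN, TNN = state0$TNN, NO3_N = state0$NO3_N,
          NO_aq = state0$NO_aq, NO2g_aq = state0$NO2g_aq,
          cum_in = 0, cum_eff = 0, cum_strip_NO = 0, cum_strip_NO2 = 0,
          cum_N2 = 0)

  kNO <- if (is.null(gas)) 0 else gas$kLa_NO
  kNO2 <- if (is.null(gas)) 0 else gas$kLa_NO2
  off <- if (is.null(gas)) 1 else gas$aeration_off_factor
  deriv <- function(t, y, p) {
    y[y < 0] <- 0
    pH <- fns$pH(t); DOt <- max(fns$DO(t), 0); Tt <- fns$temperature(t)
    I <- ec_factor * fns$conductivity(t)
    fac <- if (DOt > 0.1) 1 else off
    d <- .chem_derivs_fast(y[1L], y[2L], y[3L], y[4L], y[5L],
                           DOt, pH, Tt, I, chem, speciation,
                           fac * kNO, fac * kNO2)
    Qt <- fns$Q(t); D <- Qt / V
    TANin <- fns$TAN_in(t)
    src <- fns$f_ox(t) * Qt * TANin / V
    eff <- Qt * (y[1L] + y[2L] + y[3L] + y[4L] + y[5L])
    list(c(D * (TANin - y[1L]) - src + d[[1L]],
           -D * y[2L] + src + d[[2L]],
           -D * y[3L] + d[[3L]],
           -D * y[4L] + d[[4L]],
           -D * y[5L] + d[[5L]],
           Qt * TANin, eff,
           V * d[[7L]], V * d[[8L]],
           V * d[[6L]]),
         src = src)
  }

  jac <- function(t, y, p) {
    y[y < 0] <- 0
    pH <- fns$pH(t); DOt <- max(fns$DO(t), 0); Tt <- fns$temperature(t)
    I <- ec_factor * fns$conductivity(t)
    fac <- if (DOt > 0.1) 1 else off
    Jc <- .chem_jac_fast(y[1L], y[2L], y[3L], y[4L], y[5L],
                         DOt, pH, Tt, I, chem, speciation,
                         fac * kNO, fac * kNO2)
    Qt <- fns$Q(t); D <- Qt / V
    J <- matrix(0, 10, 10)
    J[1:5, 1:5] <- Jc[1:5, ]
    J[1:5, 1:5] <- J[1:5, 1:5] - diag(D, 5)
    J[7, 1:5] <- Qt
    J[8, 4] <- V * fac * kNO
    J[9, 5] <- V * fac * kNO2
    J[10, 1:5] <- V * Jc[6, ]
    J
  }

  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (attr(sol, "istate")[1] < 0) {
    stop("CSTR integration failed at t = ", signif(max(sol[, "time"]), 6),
         " d", call. = FALSE)
  }
  out <- as.data.frame(unclass(sol))
  neg <- names(out) %in% liquid
  out[neg][out[neg] < 0] <- 0

  series <- data.frame(time = out$time,
                       Q = fns$Q(out$time), TAN_in = fns$TAN_in(out$time),
                       pH = fns$pH(out$time), DO = fns$DO(out$time),
                       temperature = fns$temperature(out$time),
                       TAN = out$TAN, TNN = out$TNN, NO3_N = out$NO3_N,
                       NO_aq = out$NO_aq, NO2g_aq = out$NO2g_aq,
                       nitrite_source = out$src)
  storage0 <- V * sum(unlist(state0[liquid]))
  storage1 <- V * sum(out[nrow(out), liquid])
  cum <- list(influent_N = out$cum_in[nrow(out)],
              effluent_N = out$cum_eff[nrow(out)],
              stripped_NO = out$cum_strip_NO[nrow(out)],
              stripped_NO2 = out$cum_strip_NO2[nrow(out)],
              N2 = out$cum_N2[nrow(out)],
              storage_change = storage1 - storage0)
  resid <- cum$influent_N - cum$effluent_N - cum$stripped_NO -
    cum$stripped_NO2 - cum$N2 - cum$storage_change
  scale <- max(cum$influent_N, storage0, 1)
  res <- list(series = series, cumulative = cum,
              balance = list(residual_mgN = resid,
                             relative_error = abs(resid) / scale),
              volume = V,
              diagnostics = list(istate = attr(sol, "istate")))
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x$series)
  cat("CSTR simulation:", n, "output times,",
      sprintf("%.4g", x$series$time[n] - x$series$time[1]), "d\n")
  cat(sprintf("  final TAN %.1f, TNN %.1f, NO3-N %.1f mg-N/L\n",
              x$series$TAN[n], x$series$TNN[n], x$series$NO3_N[n]))
  cat(sprintf("  influent N %.1f mg; gaseous loss %.1f mg (NO %.1f, NO2 %.1f, N2 %.1f)\n",
              x$cumulative$influent_N,
              x$cumulative$stripped_NO + x$cumulative$stripped_NO2 +
                x$cumulative$N2,
              x$cumulative$stripped_NO, x$cumulative$stripped_NO2,
              x$cumulative$N2))
  cat(sprintf("  N balance relative error %.3g\n", x$balance$relative_error))
  invisible(x)
}

#' Goodness of fit of a simulation against measured series
#'
#' Computes the Nash-Sutcliffe model efficiency ([model_efficiency()])
#' for the TNN and nitrate series. Measured series may come with their
#' own time stamps, in which case the simulation is linearly
#' interpolated onto them.
#'
#' @param result a [simulate_reactor()] result.
#' @param measured_TNN,measured_NO3 numeric vectors on the result grid,
#'   or two-column data.frames `(time, value)`.
#' @return A `fit_report`: list with `E_TNN`, `E_NO3`, residual series
#'   and `n` per series.
#' @export
fit_to_measurements <- function(result, measured_TNN, measured_NO3) {
  stopifnot(inherits(result, "simulation_result"))
  one <- function(meas, sim_col) {
    if (is.data.frame(meas)) {
      tt <- meas[[1]]; yy <- meas[[2]]
      sim <- stats::approx(result$series$time, result$series[[sim_col]],
                           xout = tt)$y
      message("measured series interpolated onto its own time stamps ",
              "(linear)")
    } else {
      yy <- meas
      if (length(yy) != nrow(result$series)) {
        stop("measured series length must match the simulation grid ",
             "(or supply a (time, value) data.frame)", call. = FALSE)
      }
      sim <- result$series[[sim_col]]
    }
    list(E = model_efficiency(yy, sim), residuals = yy - sim,
         n = length(yy))
  }
  tnn <- one(measured_TNN, "TNN")
  no3 <- one(measured_NO3, "NO3_N")
  structure(list(E_TNN = tnn$E, E_NO3 = no3$E,
                 residuals_TNN = tnn$residuals,
                 residuals_NO3 = no3$residuals,
                 n = c(TNN = tnn$n, NO3 = no3$n)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("model efficiency: TNN E = %.3f, nitrate E = %.3f (n = %d, %d)\n",
              x$E_TNN, x$E_NO3, x$n[["TNN"]], x$n[["NO3"]]))
  invisible(x)
}
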