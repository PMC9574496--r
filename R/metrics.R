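# Derived process quantities: Nash-Sutcliffe efficiency, nitrite
# accumulation ratio, nitrogen-loss fraction, retention times, net growth
# rate, alkalinity-limited conversion, volumetric oxidation rates.

#' Nash-Sutcliffe model efficiency
#'
#' `E = 1 - sum((y_m - y_s)^2) / sum((y_m - mean(y_m))^2)` where `y_m`
#' is the measured and `y_s` the simulated series. E is at most 1
#' (perfect agreement); 0 means the model is no better than the mean of
#' the measurements; it is unbounded below.
#'
#' @param measured numeric vector of measured values (length >= 2,
#'   non-constant).
#' @param simulated numeric vector of the same length.
#' @return E (dimensionless scalar).
#' @examples
#' model_efficiency(1:5, c(1, 2, 3, 4, 6))  # 0.9
#' @export
model_efficiency <- function(measured, simulated) {
  if (length(measured) != length(simulated)) {
    stop("'measured' and 'simulated' must have equal length", call. = FALSE)
  }
  if (length(measured) < 2) stop("need at least 2 points", call. = FALSE)
  denom <- sum((measured - mean(measured))^2)
  if (denom == 0) {
    stop("model efficiency undefined: measured series is constant",
         call. = FALSE)
  }
  1 - sum((measured - simulated)^2) / denom
}

#' Nitrite accumulation ratio (NAR)
#'
#' Share of the oxidized nitrogen remaining as nitrite rather than being
#' converted (chemically or biologically) to nitrate:
#' `NAR = 100 * TNN / (TNN + NO3)`.
#'
#' @param TNN_eff effluent total nitrite nitrogen, mg-N/L.
#' @param NO3_eff effluent nitrate nitrogen, mg-N/L.
#' @return NAR in percent.
#' @export
nitrite_accumulation_ratio <- function(TNN_eff, NO3_eff) {
  if (any(TNN_eff < 0) || any(NO3_eff < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(TNN_eff + NO3_eff == 0)) {
    stop("NAR undefined when TNN and nitrate are both zero", call. = FALSE)
  }
  100 * TNN_eff / (TNN_eff + NO3_eff)
}

#' Net growth rate from the solids retention time
#'
#' In a chemostat without biomass retention SRT = HRT, and the net
#' growth rate at washout is `mu_net = 1 / SRT`.
#'
#' @param SRT solids retention time, d (> 0).
#' @param rounded logical; also return the one-decimal reporting value.
#' @return `mu_net` in 1/d (named vector with `reported` when
#'   `rounded`).
#' @examples
#' net_growth_rate_from_srt(1.6)  # 0.625 -> reported 0.6 1/d
#' @export
net_growth_rate_from_srt <- function(SRT, rounded = TRUE) {
  if (any(SRT <= 0)) stop("'SRT' must be > 0", call. = FALSE)
  mu <- 1 / SRT
  if (rounded) c(mu_net = mu, reported = round(mu, 1)) else mu
}

#' Hydraulic retention time
#'
#' `HRT = V / Q`.
#'
#' @param volume reactor volume, L.
#' @param Q flow, L/d (> 0).
#' @return HRT in days.
#' @export
hydraulic_retention_time <- function(volume, Q) {
  if (any(Q <= 0)) stop("'Q' must be > 0", call. = FALSE)
  volume / Q
}

#' Alkalinity-limited ammonia-to-nitrite conversion fraction
#'
#' Oxidizing one mole of ammonium to nitrite releases two proton
#' equivalents; with a molar alkalinity-to-TAN ratio `a`, only
#' `min(1, a/2)` of the TAN can be oxidized before the pH collapses. An
#' alkalinity:TAN ratio of about 1:1, typical of stored urine, limits
#' the conversion to about 50%.
#'
#' @param alkalinity proton-accepting equivalents, mol/L.
#' @param TAN_molar total ammoniacal nitrogen, mol-N/L (> 0).
#' @return Conversion fraction in \[0, 1\].
#' @export
alkalinity_limited_fraction <- function(alkalinity, TAN_molar) {
  if (any(alkalinity < 0)) stop("'alkalinity' must be >= 0", call. = FALSE)
  if (any(TAN_molar <= 0)) stop("'TAN_molar' must be > 0", call. = FALSE)
  pmin(1, alkalinity / (2 * TAN_molar))
}

#' Nitrogen balance container
#'
#' @param influent_N nitrogen load fed, mg-N.
#' @param effluent_N dissolved nitrogen leaving with the effluent, mg-N.
#' @param storage_change change of dissolved nitrogen inventory, mg-N.
#' @param gaseous_loss known stripped/gaseous nitrogen, mg-N (optional
#'   bookkeeping; the loss fraction is computed as the residual).
#' @return An object of class `nitrogen_balance`.
#' @export
nitrogen_balance <- function(influent_N, effluent_N, storage_change = 0,
                             gaseous_loss = NA_real_) {
  vals <- c(influent_N, effluent_N, storage_change)
  if (any(!is.finite(vals))) {
    stop("balance components must be finite", call. = FALSE)
  }
  structure(list(influent_N = influent_N, effluent_N = effluent_N,
                 storage_change = storage_change,
                 gaseous_loss = gaseous_loss),
            class = "nitrogen_balance")
}

#' Nitrogen-loss fraction
#'
#' Loss of nitrogen relative to the influent load, computed as the
#' residual of the dissolved balance:
#' `100 * (influent - effluent - storage change) / influent`. Only
#' dissolved nitrogen enters the influent/effluent terms; whatever is
#' missing left as gas.
#'
#' @param balance a [nitrogen_balance()], or a [simulate_reactor()]
#'   result (its cumulative masses are used).
#' @param mode for simulation results only: `"cumulative"` (default)
#'   computes the loss from cumulative masses; `"concentration"` from
#'   the time-averaged ratio of dissolved effluent to influent
#'   concentration (ignores storage; the convention used in some
#'   operating reports). The two differ under strongly varying flow.
#' @return Loss in percent of the influent nitrogen.
#' @export
nitrogen_loss_fraction <- function(balance,
                                   mode = c("cumulative", "concentration")) {
  mode <- match.arg(mode)
  if (inherits(balance, "simulation_result")) {
    if (mode == "concentration") {
      s <- balance$series
      diss <- s$TAN + s$TNN + s$NO3_N + s$NO_aq + s$NO2g_aq
      return(100 * (1 - mean(diss) / mean(s$TAN_in)))
    }
    cum <- balance$cumulative
    balance <- nitrogen_balance(cum$influent_N, cum$effluent_N,
                                cum$storage_change,
                                cum$stripped_NO + cum$stripped_NO2 + cum$N2)
  }
  stopifnot(inherits(balance, "nitrogen_balance"))
  if (balance$influent_N <= 0) {
    stop("'influent_N' must be > 0", call. = FALSE)
  }
  100 * (balance$influent_N - balance$effluent_N -
           balance$storage_change) / balance$influent_N
}

#' Volumetric ammonia and nitrite oxidation rates
#'
#' Reconstructs rates from concentration series by the reactor mass
#' balance, including the accumulation term:
#' `AOR = (Q/V) (TAN_in - TAN) - dTAN/dt` and
#' `NOR = (Q/V) NO3 + dNO3/dt` (nitrate assumed absent from the
#' influent). Derivatives use centered finite differences, optionally
#' smoothed with a centered running mean.
#'
#' @param timeline an [operation_timeline()].
#' @param reactor_series data.frame with columns `time`, `TAN`, `NO3_N`
#'   on the same grid as the timeline.
#' @param smooth odd window length for a running-mean smoother of the
#'   differentiated series (default 0 = none).
#' @return data.frame with `time`, `AOR`, `NOR` in mg-N/(L d).
#' @export
volumetric_rates <- function(timeline, reactor_series, smooth = 0) {
  stopifnot(inherits(timeline, "operation_timeline"))
  if (!all(c("time", "TAN", "NO3_N") %in% names(reactor_series))) {
    stop("'reactor_series' needs columns time, TAN, NO3_N", call. = FALSE)
  }
  if (length(timeline$time) != length(reactor_series$time) ||
      any(abs(timeline$time - reactor_series$time) > 1e-9)) {
    stop("timeline and reactor series must share the same time grid",
         call. = FALSE)
  }
  V <- attr(timeline, "volume")
  D <- timeline$Q / V
  ddt <- function(y) {
    t <- timeline$time
    n <- length(y)
    d <- numeric(n)
    d[1] <- (y[2] - y[1]) / (t[2] - t[1])
    d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    if (smooth >= 3) {
      k <- rep(1 / smooth, smooth)
      d <- stats::filter(d, k, sides = 2)
      d[is.na(d)] <- 0
    }
    as.numeric(d)
  }
  AOR <- D * (timeline$TAN_in - reactor_series$TAN) - ddt(reactor_series$TAN)
  NOR <- D * reactor_series$NO3_N + ddt(reactor_series$NO3_N)
  data.frame(time = timeline$time, AOR = AOR, NOR = NOR)
}
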