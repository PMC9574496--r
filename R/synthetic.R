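# Seeded generator of synthetic reactor-operation timelines emulating an
# acidic urine-nitritation CSTR: pH held in a narrow band by on-off
# influent dosing, DO held by on-off aeration, urine-strength influent
# with tank-change steps, and the four classes of process disturbance
# observed in such reactors. The pH dynamics are phenomenological
# (relaxation toward band edges); the generator is intentionally
# independent of the chemistry module it helps to test.

# run `code` with a private RNG stream; the global seed is untouched
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scenario configuration for the timeline generator
#'
#' Ranges mirror typical acidic urine-nitritation operation:
#' urine-strength influent TAN (1000-3500 mg-N/L) stepping at tank
#' changes, pH controlled in a 4.9-5.0 band by influent dosing, DO
#' controlled between 4 and 6 mg/L, 25 degC, hydraulic retention times
#' of 1.6-10 d, and brackish-to-saline conductivity.
#'
#' @param duration scenario length, d.
#' @param dt time resolution, d.
#' @param TAN_in_range influent TAN range, mg-N/L.
#' @param pH_band pH control band (low, high).
#' @param DO_band DO control band, mg-O2/L.
#' @param temperature base temperature, degC.
#' @param HRT_range admissible hydraulic retention times, d; one target
#'   is drawn per scenario.
#' @param EC_range conductivity range, mS/cm.
#' @param volume reactor volume, L.
#' @param f_ox imposed ammonia-to-nitrite conversion fraction.
#' @param pH_rate_down,pH_rate_up pH drift rates during acidification /
#'   dosing, pH units per day.
#' @param DO_period aeration on-off cycle period, d.
#' @param tank_interval_range days between influent tank changes.
#' @param noise_sd named list of additive Gaussian noise standard
#'   deviations per channel (`TAN_in`, `DO`, `temperature`,
#'   `conductivity`; pH is controller-bound and left noise-free by
#'   default).
#' @param seed integer seed making generation fully reproducible.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(duration = 100, dt = 0.01,
                            TAN_in_range = c(1000, 3500),
                            pH_band = c(4.9, 5.0), DO_band = c(4, 6),
                            temperature = 25, HRT_range = c(1.6, 10),
                            EC_range = c(25, 40), volume = 12,
                            f_ox = 0.5, pH_rate_down = 2, pH_rate_up = 4,
                            DO_period = 0.05,
                            tank_interval_range = c(10, 30),
                            noise_sd = list(TAN_in = 25, DO = 0.1,
                                            temperature = 0.2,
                                            conductivity = 0.5),
                            seed = 1) {
  if (duration <= 0 || dt <= 0) {
    stop("'duration' and 'dt' must be > 0", call. = FALSE)
  }
  ordered2 <- function(x, nm) {
    if (length(x) != 2 || diff(x) < 0) {
      stop("'", nm, "' must be an ordered (low, high) pair", call. = FALSE)
    }
    as.numeric(x)
  }
  cfg <- list(duration = duration, dt = dt,
              TAN_in_range = ordered2(TAN_in_range, "TAN_in_range"),
              pH_band = ordered2(pH_band, "pH_band"),
              DO_band = ordered2(DO_band, "DO_band"),
              temperature = temperature,
              HRT_range = ordered2(HRT_range, "HRT_range"),
              EC_range = ordered2(EC_range, "EC_range"),
              volume = volume, f_ox = f_ox,
              pH_rate_down = pH_rate_down, pH_rate_up = pH_rate_up,
              DO_period = DO_period,
              tank_interval_range = ordered2(tank_interval_range,
                                             "tank_interval_range"),
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a synthetic operation timeline
#'
#' Pure function of the configuration (including its seed): the same
#' config yields the identical timeline. pH oscillates inside the
#' control band (influent dosing on-off controller: drift down during
#' oxidation, pulled up while the pump runs); Q toggles with the dosing
#' phase such that the mean flow meets the drawn target HRT; DO follows
#' a triangular on-off wave inside its band; influent TAN is piecewise
#' constant with steps at tank changes; conductivity performs a slow
#' mean-reverting walk inside its range.
#'
#' @param config a [scenario_config()].
#' @return An [operation_timeline()].
#' @export
generate_timeline <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  with_local_seed(config$seed, {
    t <- seq(0, config$duration, by = config$dt)
    n <- length(t)

    # pH: triangle oscillation inside the band
    band <- config$pH_band
    width <- max(band[2] - band[1], 1e-6)
    pH <- numeric(n)
    pH[1] <- band[2]
    dosing <- logical(n)   # pump on?
    up <- FALSE
    for (i in 2:n) {
      if (up) {
        pH[i] <- pH[i - 1] + config$pH_rate_up * config$dt
        if (pH[i] >= band[2]) { pH[i] <- band[2]; up <- FALSE }
      } else {
        pH[i] <- pH[i - 1] - config$pH_rate_down * config$dt
        if (pH[i] <= band[1]) { pH[i] <- band[1]; up <- TRUE }
      }
      dosing[i] <- up
    }

    # flow: on-off with the dosing phase, sized to the target HRT
    HRT_target <- stats::runif(1, config$HRT_range[1], config$HRT_range[2])
    duty <- max(mean(dosing), 1e-3)
    Q_on <- config$volume / HRT_target / duty
    Q <- ifelse(dosing, Q_on, 0)

    # influent TAN: steps at tank changes
    TAN_in <- numeric(n)
    pos <- 0
    while (pos < config$duration) {
      len <- stats::runif(1, config$tank_interval_range[1],
                          config$tank_interval_range[2])
      idx <- t >= pos & t <= pos + len
      TAN_in[idx] <- stats::runif(1, config$TAN_in_range[1],
                                  config$TAN_in_range[2])
      pos <- pos + len
    }
    TAN_in <- TAN_in + stats::rnorm(n, 0, config$noise_sd$TAN_in %||% 0)
    TAN_in <- pmin(pmax(TAN_in, config$TAN_in_range[1]),
                   config$TAN_in_range[2])

    # DO: triangular on-off wave inside its band
    dob <- config$DO_band
    phase <- (t %% config$DO_period) / config$DO_period
    DO <- ifelse(phase < 0.5,
                 dob[1] + (dob[2] - dob[1]) * 2 * phase,
                 dob[2] - (dob[2] - dob[1]) * 2 * (phase - 0.5))
    DO <- DO + stats::rnorm(n, 0, config$noise_sd$DO %||% 0)
    DO <- pmin(pmax(DO, dob[1]), dob[2])

    temperature <- config$temperature +
      stats::rnorm(n, 0, config$noise_sd$temperature %||% 0)

    # conductivity: mean-reverting walk, clipped to range
    ecr <- config$EC_range
    ec <- numeric(n)
    ec[1] <- mean(ecr)
    innov <- stats::rnorm(n, 0, config$noise_sd$conductivity %||% 0)
    for (i in 2:n) {
      ec[i] <- ec[i - 1] + 0.02 * (mean(ecr) - ec[i - 1]) +
        innov[i] * sqrt(config$dt)
    }
    ec <- pmin(pmax(ec, ecr[1]), ecr[2])

    operation_timeline(time = t, Q = Q, TAN_in = TAN_in, pH = pH, DO = DO,
                       temperature = temperature, conductivity = ec,
                       volume = config$volume, f_ox = config$f_ox)
  })
}

#' Disturbance specification
#'
#' The four disturbance classes of acidic nitritation operation:
#' `influent_stop` (pump failure: no dosing, pH drifts toward its
#' floor), `aeration_stop` (anoxia for hours), `overpumping`
#' (uncontrolled continuous dosing: pH rises toward alkaline urine,
#' washout-scale flow) and `overheating` (temperature control failure).
#'
#' @param kind one of `"influent_stop"`, `"aeration_stop"`,
#'   `"overpumping"`, `"overheating"`.
#' @param start window start, d.
#' @param duration window length, d. For `aeration_stop`, `NULL` draws
#'   a duration between 3 and 15 hours (seeded).
#' @param magnitude kind-specific level: pH floor for `influent_stop`
#'   (default 4), pH ceiling for `overpumping` (default 8.5),
#'   temperature peak for `overheating` (default 33 degC); ignored for
#'   `aeration_stop`.
#' @param tau relaxation time constant of the disturbed channel, d.
#' @param seed seed for the drawn `aeration_stop` duration.
#' @return An object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(kind, start, duration = NULL,
                             magnitude = NULL, tau = 0.5, seed = 1) {
  kinds <- c("influent_stop", "aeration_stop", "overpumping", "overheating")
  kind <- match.arg(kind, kinds)
  if (is.null(duration)) {
    if (kind == "aeration_stop") {
      duration <- with_local_seed(seed, stats::runif(1, 3 / 24, 15 / 24))
    } else {
      stop("'duration' is required for kind '", kind, "'", call. = FALSE)
    }
  }
  if (start < 0 || duration <= 0) {
    stop("'start' must be >= 0 and 'duration' > 0", call. = FALSE)
  }
  if (is.null(magnitude)) {
    magnitude <- switch(kind, influent_stop = 4, aeration_stop = 0,
                        overpumping = 8.5, overheating = 33)
  }
  structure(list(kind = kind, start = start, duration = duration,
                 magnitude = magnitude, tau = tau),
            class = "disturbance_spec")
}

#' Inject a disturbance into a timeline
#'
#' Overwrites the affected channels on the disturbance window and adds a
#' relaxation back to normal operation afterwards. `influent_stop` sets
#' `Q = 0` and lets pH relax exponentially toward the configured floor;
#' `aeration_stop` sets `DO = 0`; `overpumping` imposes a
#' one-reactor-volume-per-half-day flow and pulls pH up toward the
#' ceiling; `overheating` pulls temperature toward its peak.
#'
#' @param timeline an [operation_timeline()].
#' @param spec a [disturbance_spec()].
#' @return The modified [operation_timeline()].
#' @export
inject_disturbance <- function(timeline, spec) {
  stopifnot(inherits(timeline, "operation_timeline"),
            inherits(spec, "disturbance_spec"))
  t <- timeline$time
  t0 <- spec$start; t1 <- spec$start + spec$duration
  if (t0 < t[1] || t1 > t[length(t)]) {
    stop("disturbance window [", t0, ", ", t1,
         "] lies outside the timeline", call. = FALSE)
  }
  win <- t >= t0 & t <= t1
  after <- t > t1
  relax_to <- function(from, target, tau, tvec, tstart) {
    target + (from - target) * exp(-(tvec - tstart) / tau)
  }
  switch(spec$kind,
    influent_stop = {
      timeline$Q[win] <- 0
      pH_start <- timeline$pH[which(win)[1]]
      timeline$pH[win] <- relax_to(pH_start, spec$magnitude,
                                   spec$tau, t[win], t0)
      pH_end <- timeline$pH[max(which(win))]
      rec <- relax_to(pH_end, pH_start, spec$tau / 2, t[after], t1)
      timeline$pH[after] <- pmin(timeline$pH[after], rec)
    },
    aeration_stop = {
      timeline$DO[win] <- 0
    },
    overpumping = {
      vol <- attr(timeline, "volume")
      timeline$Q[win] <- 2 * vol        # one reactor volume per half day
      pH_start <- timeline$pH[which(win)[1]]
      timeline$pH[win] <- pmin(spec$magnitude,
                               relax_to(pH_start, spec$magnitude,
                                        spec$tau, t[win], t0))
      pH_end <- timeline$pH[max(which(win))]
      rec <- relax_to(pH_end, pH_start, spec$tau / 2, t[after], t1)
      timeline$pH[after] <- pmax(timeline$pH[after], rec)
    },
    overheating = {
      T_start <- timeline$temperature[which(win)[1]]
      timeline$temperature[win] <- relax_to(T_start, spec$magnitude,
                                            spec$tau, t[win], t0)
      T_end <- timeline$temperature[max(which(win))]
      rec <- relax_to(T_end, mean(timeline$temperature[!win]),
                      spec$tau / 2, t[after], t1)
      timeline$temperature[after] <- pmax(timeline$temperature[after], rec)
    })
  timeline
}

#' Additive measurement noise
#'
#' Seeded Gaussian noise clipped at physical bounds.
#'
#' @param series numeric vector.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param lower,upper clipping bounds (defaults: non-negative,
#'   unbounded above; use `c(0, 14)` style bounds for pH).
#' @return The noisy series.
#' @export
add_measurement_noise <- function(series, sigma, seed = 1,
                                  lower = 0, upper = Inf) {
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (sigma == 0) return(series)
  with_local_seed(seed, {
    pmin(pmax(series + stats::rnorm(length(series), 0, sigma), lower),
         upper)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
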