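# Limitation/inhibition factors used to interpret short-term
# respirometric activity of acid-tolerant ammonia oxidizers: Monod DO
# and NH3 limitation, non-competitive HNO2 inhibition, a threshold-linear
# salinity factor, and relative activity from oxygen uptake rates.
# These are descriptive utilities; they are deliberately not wired into
# the reactor simulation, whose chemistry is purely abiotic.

#' Activity kinetic parameters
#'
#' Defaults reflect values reported for acid-tolerant and conventional
#' ammonia oxidizers: DO affinity 0.8 mg-O2/L, HNO2 half-inhibition
#' constants in the 0.07-2.8 mg-N/L range for conventional AOB, and a
#' salinity effect appearing above 20 mS/cm.
#'
#' @param K_I_HNO2 HNO2 half-inhibition constant, mg-N/L.
#' @param K_S_DO DO half-saturation constant, mg-O2/L.
#' @param K_S_NH3 NH3 half-saturation constant, mg-N/L (sub-microgram
#'   affinities are typical of acid-tolerant AOB).
#' @param salinity_threshold conductivity above which activity declines,
#'   mS/cm.
#' @param salinity_slope decline in percent activity per mS/cm above the
#'   threshold. The default (2.5 %/mS/cm) keeps partial activity over
#'   the conductivity range of nitrified urine; only the threshold
#'   itself is well constrained by observation, so calibrate the slope
#'   to the matrix at hand.
#' @return An object of class `activity_params`.
#' @export
activity_params <- function(K_I_HNO2 = 2.8, K_S_DO = 0.8,
                            K_S_NH3 = 0.001, salinity_threshold = 20,
                            salinity_slope = 2.5) {
  ks <- c(K_I_HNO2 = K_I_HNO2, K_S_DO = K_S_DO, K_S_NH3 = K_S_NH3,
          salinity_threshold = salinity_threshold)
  if (any(ks <= 0)) stop("kinetic constants must be > 0", call. = FALSE)
  if (salinity_slope < 0) stop("'salinity_slope' must be >= 0", call. = FALSE)
  structure(c(as.list(ks), list(salinity_slope = salinity_slope)),
            class = "activity_params")
}

#' Non-competitive free nitrous acid inhibition
#'
#' `factor = K_I / (K_I + S)`; percent inhibition is
#' `100 * (1 - factor)`. With `K_I = 2.8` mg-N/L, an HNO2 concentration
#' of 30 mg-N/L gives 91% inhibition.
#'
#' @param S_HNO2 free nitrous acid, mg-N/L.
#' @param K_I half-inhibition constant, mg-N/L.
#' @return Multiplier in (0, 1].
#' @export
hno2_inhibition_factor <- function(S_HNO2, K_I = 2.8) {
  if (any(S_HNO2 < 0)) stop("'S_HNO2' must be >= 0", call. = FALSE)
  if (any(K_I <= 0)) stop("'K_I' must be > 0", call. = FALSE)
  K_I / (K_I + S_HNO2)
}

#' Monod dissolved-oxygen limitation
#'
#' `factor = DO / (K_S + DO)`.
#'
#' @param DO dissolved oxygen, mg-O2/L.
#' @param K_S half-saturation constant, mg-O2/L (default 0.8).
#' @return Multiplier in \[0, 1).
#' @export
do_limitation_factor <- function(DO, K_S = 0.8) {
  if (any(DO < 0)) stop("'DO' must be >= 0", call. = FALSE)
  if (any(K_S <= 0)) stop("'K_S' must be > 0", call. = FALSE)
  DO / (K_S + DO)
}

#' Monod free-ammonia limitation
#'
#' `factor = S / (K_S + S)`.
#'
#' @param S_NH3 free ammonia, mg-N/L.
#' @param K_S half-saturation constant, mg-N/L.
#' @return Multiplier in \[0, 1).
#' @export
nh3_limitation_factor <- function(S_NH3, K_S = 0.001) {
  if (any(S_NH3 < 0)) stop("'S_NH3' must be >= 0", call. = FALSE)
  if (any(K_S <= 0)) stop("'K_S' must be > 0", call. = FALSE)
  S_NH3 / (K_S + S_NH3)
}

#' Threshold-linear salinity factor
#'
#' Full activity up to the threshold conductivity, then a linear decline
#' of `salinity_slope` percent per mS/cm, floored at zero.
#'
#' @param EC conductivity, mS/cm.
#' @param params an [activity_params()].
#' @return Multiplier in \[0, 1\].
#' @export
salinity_factor <- function(EC, params = activity_params()) {
  if (any(EC < 0)) stop("'EC' must be >= 0", call. = FALSE)
  excess <- pmax(0, EC - params$salinity_threshold)
  pmax(0, 1 - params$salinity_slope / 100 * excess)
}

#' Relative activity from oxygen uptake rates
#'
#' Ratio of a test oxygen uptake rate to the reference OUR measured
#' under unchanged conditions.
#'
#' @param OUR_test test oxygen uptake rate, mg-O2/(L h) (>= 0).
#' @param OUR_ref reference OUR, mg-O2/(L h) (> 0).
#' @return Dimensionless relative activity.
#' @export
relative_activity <- function(OUR_test, OUR_ref) {
  if (any(OUR_ref <= 0)) stop("'OUR_ref' must be > 0", call. = FALSE)
  if (any(OUR_test < 0)) stop("'OUR_test' must be >= 0", call. = FALSE)
  OUR_test / OUR_ref
}

#' All activity factors for one set of conditions
#'
#' Evaluates every mechanism and their product. The multiplicative
#' combination is the activated-sludge-model convention; note that HNO2
#' toxicity beyond reversible inhibition (irreversible damage at very
#' high HNO2) is not represented.
#'
#' @param HNO2 free nitrous acid, mg-N/L.
#' @param DO dissolved oxygen, mg-O2/L.
#' @param NH3 free ammonia, mg-N/L.
#' @param EC conductivity, mS/cm.
#' @param params an [activity_params()].
#' @return An object of class `activity_factors`: list with one
#'   multiplier per mechanism and `combined`.
#' @export
activity_factors <- function(HNO2, DO, NH3, EC,
                             params = activity_params()) {
  f <- list(hno2_inhibition = hno2_inhibition_factor(HNO2, params$K_I_HNO2),
            do_limitation = do_limitation_factor(DO, params$K_S_DO),
            nh3_limitation = nh3_limitation_factor(NH3, params$K_S_NH3),
            salinity = salinity_factor(EC, params))
  f$combined <- combined_activity(f[1:4])
  structure(f, class = "activity_factors")
}

#' Combined activity multiplier
#'
#' Product of individual factors, each of which must lie in \[0, 1\].
#'
#' @param factors numeric vector or list of multipliers.
#' @return The product (dimensionless).
#' @export
combined_activity <- function(factors) {
  f <- unlist(factors)
  if (any(f < 0 | f > 1)) {
    stop("all factors must lie in [0, 1]", call. = FALSE)
  }
  prod(f)
}
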