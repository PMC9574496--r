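# Acid-base speciation of the TAN (NH4+/NH3) and TNN (NO2-/HNO2) pairs.
# All nitrogen concentrations are expressed as mg-N/L throughout the package.

#' Speciation constants
#'
#' Bundles the temperature functions of the two dissociation constants and
#' the parameters of the Davies activity-coefficient model.
#'
#' The defaults are the classical choices of the nitrification literature:
#' `pKa(NH4+) = 0.09018 + 2729.92 / T[K]` and, for nitrous acid,
#' `ln Ka(HNO2) = -2300 / T[K]`. Both are stored as coefficient pairs
#' `(a, b)` meaning `pKa = a + b / T[K]` so alternative sources can be
#' dropped in. Activity correction uses the Davies equation,
#' `log10(gamma) = -A * z^2 * (sqrt(I) / (1 + sqrt(I)) - c * I)`, with
#' `A = 0.509` (25 degC) and linear term `c = 0.3`.
#'
#' @param pKa_NH4_coeffs numeric length-2, `(a, b)` of `pKa = a + b/T[K]`
#'   for ammonium.
#' @param pKa_HNO2_coeffs numeric length-2, same convention, for nitrous
#'   acid. The default is `-2300/T` converted from natural log,
#'   i.e. `b = 2300 / ln(10)`.
#' @param davies_A Debye-Huckel `A` coefficient (dimensionless).
#' @param davies_linear linear-term coefficient `c` of the Davies equation.
#' @return An object of class `speciation_constants`.
#' @examples
#' sc <- speciation_constants()
#' pKa_NH4(25, sc)   # about 9.25
#' pKa_HNO2(25, sc)  # about 3.35
#' @export
speciation_constants <- function(pKa_NH4_coeffs = c(0.09018, 2729.92),
                                 pKa_HNO2_coeffs = c(0, 2300 / log(10)),
                                 davies_A = 0.509,
                                 davies_linear = 0.3) {
  stopifnot(length(pKa_NH4_coeffs) == 2, length(pKa_HNO2_coeffs) == 2)
  if (!is.numeric(davies_A) || davies_A <= 0) {
    stop("'davies_A' must be a positive number", call. = FALSE)
  }
  out <- list(
    pKa_NH4_coeffs = as.numeric(pKa_NH4_coeffs),
    pKa_HNO2_coeffs = as.numeric(pKa_HNO2_coeffs),
    davies_A = as.numeric(davies_A),
    davies_linear = as.numeric(davies_linear)
  )
  class(out) <- "speciation_constants"
  out
}

#' @rdname speciation_constants
#' @param temperature temperature in degrees Celsius.
#' @param consts a [speciation_constants()] object.
#' @export
pKa_NH4 <- function(temperature, consts = speciation_constants()) {
  consts$pKa_NH4_coeffs[1] + consts$pKa_NH4_coeffs[2] / (temperature + 273.15)
}

#' @rdname speciation_constants
#' @export
pKa_HNO2 <- function(temperature, consts = speciation_constants()) {
  consts$pKa_HNO2_coeffs[1] + consts$pKa_HNO2_coeffs[2] / (temperature + 273.15)
}

#' Ionic context of a solution
#'
#' Ionic strength, temperature and (optionally) conductivity at one
#' instant. When `ionic_strength` is missing but `conductivity` is given,
#' the ionic strength is estimated with
#' [ionic_strength_from_conductivity()].
#'
#' @param ionic_strength ionic strength in mol/L.
#' @param temperature temperature in degrees Celsius (0-45).
#' @param conductivity electrical conductivity in mS/cm, optional.
#' @param ec_factor empirical conversion factor, mol/L per mS/cm.
#' @return An object of class `ionic_context`.
#' @export
ionic_context <- function(ionic_strength = NULL, temperature = 25,
                          conductivity = NULL, ec_factor = 0.016) {
  if (is.null(ionic_strength)) {
    ionic_strength <- if (is.null(conductivity)) 0 else
      ionic_strength_from_conductivity(conductivity, ec_factor)
  }
  if (ionic_strength < 0) {
    stop("'ionic_strength' must be >= 0", call. = FALSE)
  }
  if (temperature < 0 || temperature > 45) {
    stop("'temperature' must lie in [0, 45] degC", call. = FALSE)
  }
  structure(list(ionic_strength = ionic_strength,
                 temperature = temperature,
                 conductivity = conductivity),
            class = "ionic_context")
}

#' Estimate ionic strength from conductivity
#'
#' Linear empirical rule `I = factor * EC`. The default factor of
#' 0.016 mol/L per mS/cm is the common rule of thumb for mixed
#' electrolytes; override it when a matrix-specific calibration is
#' available.
#'
#' @param conductivity conductivity in mS/cm.
#' @param factor mol/L per mS/cm, must be positive.
#' @return Ionic strength in mol/L.
#' @examples
#' ionic_strength_from_conductivity(25)  # 0.40 mol/L
#' @export
ionic_strength_from_conductivity <- function(conductivity, factor = 0.016) {
  if (any(conductivity < 0)) stop("'conductivity' must be >= 0", call. = FALSE)
  if (factor <= 0) stop("'factor' must be > 0", call. = FALSE)
  factor * conductivity
}

#' Single-ion activity coefficient (Davies equation)
#'
#' `gamma = 10^(-A * z^2 * (sqrt(I)/(1 + sqrt(I)) - c * I))`. Neutral
#' species (`charge = 0`) and zero ionic strength give `gamma = 1`.
#'
#' @param charge integer ion charge (sign irrelevant, enters squared).
#' @param ctx an [ionic_context()].
#' @param consts a [speciation_constants()] object.
#' @return Activity coefficient in (0, 1].
#' @examples
#' activity_coefficient(1, ionic_context(ionic_strength = 0.1))  # 0.7816
#' @export
activity_coefficient <- function(charge, ctx = ionic_context(),
                                 consts = speciation_constants()) {
  I <- ctx$ionic_strength
  if (I < 0) stop("ionic strength must be >= 0", call. = FALSE)
  if (charge == 0 || I == 0) return(1)
  sqI <- sqrt(I)
  expo <- -consts$davies_A * charge^2 *
    (sqI / (1 + sqI) - consts$davies_linear * I)
  10^expo
}

#' Free ammonia (NH3-N) from total ammoniacal nitrogen
#'
#' Splits TAN into NH3-N and NH4+-N using the temperature-dependent
#' ammonium dissociation constant with an ionic-strength (activity)
#' correction. pH is treated as hydrogen-ion activity (a glass-electrode
#' reading), so only the charged species NH4+ carries an activity
#' coefficient; the conditional constant is
#' `pKa' = pKa - log10(gamma_NH4)` and the free fraction
#' `f = r / (1 + r)` with `r = 10^(pH - pKa')`.
#'
#' @param TAN total ammoniacal nitrogen in mg-N/L.
#' @param pH reactor pH (0 < pH < 14).
#' @param ctx an [ionic_context()].
#' @param consts a [speciation_constants()] object.
#' @return NH3-N in mg-N/L. NH4+-N is `TAN - free_ammonia(...)` exactly.
#' @examples
#' free_ammonia(1000, pH = 7)  # about 5.7 mg-N/L at 25 degC, I = 0
#' @export
free_ammonia <- function(TAN, pH, ctx = ionic_context(),
                         consts = speciation_constants()) {
  check_total_ph(TAN, pH, "TAN")
  gamma <- activity_coefficient(1L, ctx, consts)
  pKa_cond <- pKa_NH4(ctx$temperature, consts) - log10(gamma)
  r <- 10^(pH - pKa_cond)
  TAN * r / (1 + r)
}

#' Free nitrous acid (HNO2-N) from total nitrite nitrogen
#'
#' Splits TNN into HNO2-N and NO2--N analogously to [free_ammonia()].
#' Only the nitrite anion carries an activity coefficient; the free
#' fraction is `g = 1 / (1 + 10^(pH - pKa) / gamma_NO2)`, strictly
#' decreasing in pH.
#'
#' @param TNN total nitrite nitrogen in mg-N/L.
#' @inheritParams free_ammonia
#' @return HNO2-N in mg-N/L. NO2--N is `TNN - free_nitrous_acid(...)`.
#' @examples
#' free_nitrous_acid(500, pH = 4.2)  # > 40 mg-N/L at 25 degC
#' @export
free_nitrous_acid <- function(TNN, pH, ctx = ionic_context(),
                              consts = speciation_constants()) {
  check_total_ph(TNN, pH, "TNN")
  gamma <- activity_coefficient(-1L, ctx, consts)
  pKa <- pKa_HNO2(ctx$temperature, consts)
  ratio <- 10^(pH - pKa) / gamma   # [NO2-]/[HNO2]
  TNN / (1 + ratio)
}

#' Full four-species speciation at one instant
#'
#' Convenience wrapper returning all four nitrogen species of the two
#' acid-base pairs.
#'
#' @inheritParams free_ammonia
#' @param TNN total nitrite nitrogen in mg-N/L.
#' @return A named list with `NH3_N`, `NH4_N`, `HNO2_N`, `NO2_N`
#'   (mg-N/L).
#' @export
speciate <- function(TAN, TNN, pH, ctx = ionic_context(),
                     consts = speciation_constants()) {
  nh3 <- free_ammonia(TAN, pH, ctx, consts)
  fna <- free_nitrous_acid(TNN, pH, ctx, consts)
  list(NH3_N = nh3, NH4_N = TAN - nh3, HNO2_N = fna, NO2_N = TNN - fna)
}

check_total_ph <- function(total, pH, what) {
  if (any(total < 0)) stop("'", what, "' must be >= 0", call. = FALSE)
  if (any(pH <= 0) || any(pH >= 14)) {
    stop("'pH' must lie in (0, 14)", call. = FALSE)
  }
  invisible(TRUE)
}
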