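# Structured-text (YAML) configuration for the kinetic and gas-transfer
# parameters, schema-checked on load so a malformed file fails loudly
# rather than silently defaulting.

.kinetics_schema <- c("k_hno2_disp", "k_no_no2_recomb", "k_no_oxidation",
                      "k_no2_hydrolysis", "k_no3_recomb",
                      "k_n2o3_formation", "k_n2o3_decomp", "k_n2o3_nh3")

#' Read / write a kinetics configuration file
#'
#' YAML with one `constants` block (value + units per rate constant), an
#' `nh3_branch` switch, a `theta` temperature correction, and an
#' optional `gas_transfer` block. Values round-trip exactly:
#' `read_kinetics_config(write_kinetics_config(p, f))` reproduces `p`.
#'
#' @param path file path.
#' @return `read_kinetics_config()` returns a list with elements
#'   `chem` ([chem_kinetics_params()]) and `gas`
#'   ([gas_transfer_params()] or `NULL`).
#' @export
read_kinetics_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constants)) {
    stop("kinetics config: missing 'constants' block", call. = FALSE)
  }
  miss <- setdiff(.kinetics_schema, names(cfg$constants))
  if (length(miss) > 0) {
    stop("kinetics config: missing constants: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(cfg$constants, function(x) {
    v <- if (is.list(x)) x$value else x
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop("kinetics config: every constant needs one numeric value >= 0",
           call. = FALSE)
    }
    v
  })
  chem <- do.call(chem_kinetics_params,
                  c(vals[.kinetics_schema],
                    list(nh3_branch = isTRUE(cfg$nh3_branch %||% TRUE),
                         theta = cfg$theta %||% 1)))
  gas <- NULL
  if (!is.null(cfg$gas_transfer)) {
    g <- cfg$gas_transfer
    gas <- gas_transfer_params(kLa_NO = g$kLa_NO %||% 100,
                               kLa_NO2 = g$kLa_NO2 %||% 50,
                               aeration_off_factor =
                                 g$aeration_off_factor %||% 0.1)
  }
  list(chem = chem, gas = gas)
}

#' @rdname read_kinetics_config
#' @param chem a [chem_kinetics_params()].
#' @param gas optional [gas_transfer_params()].
#' @export
write_kinetics_config <- function(chem, path, gas = NULL) {
  stopifnot(inherits(chem, "chem_kinetics_params"))
  units <- attr(chem, "units")
  constants <- lapply(.kinetics_schema, function(nm) {
    list(value = chem[[nm]], units = unname(units[nm]))
  })
  names(constants) <- .kinetics_schema
  cfg <- list(constants = constants, nh3_branch = chem$nh3_branch,
              theta = chem$theta)
  if (!is.null(gas)) {
    cfg$gas_transfer <- list(kLa_NO = gas$kLa_NO, kLa_NO2 = gas$kLa_NO2,
                             aeration_off_factor = gas$aeration_off_factor)
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
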