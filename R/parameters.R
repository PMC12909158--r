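# Parameter tables, configuration objects, validation and unit handling.
#
# The user-facing interface works in the units an EVLP monitor reports
# ("table units"): static compliance in mL/cmH2O, perfusate flow in L/min,
# acidity as pH.  Internally everything is canonical: time s, volume L,
# flow L/s, airway pressures cmH2O, gas tensions mmHg, concentrations
# mol/L.  Conversions happen once, at the configuration boundary.

#' Parameter reference table
#'
#' Normal ranges, default values and units for every model parameter and
#' physical constant: the clinically measured ventilation/perfusion inputs,
#' the intrinsic (estimated) lung properties, and the physico-chemical
#' constants of the acellular perfusate. Ranges and defaults are in the
#' user-facing ("table") units; `scale` converts a table-unit value to the
#' canonical internal unit (multiplicative, pH excepted).
#'
#' @return A data.frame with columns `name`, `group` (`clinical`,
#'   `intrinsic` or `constant`), `min`, `max`, `default`, `unit`, `scale`.
#' @export
evlp_ranges <- function() {
  df <- rbind(
    data.frame(
      name = c("Vt", "T_insp", "T_exp", "PEEP", "FiO2", "C_stat", "Q",
               "pH", "P_PA_O2", "P_PA_CO2"),
      group = "clinical",
      min = c(0.2, 1, 2, 5, 0.21, 20, 0.5, 7.0, 40, 20),
      max = c(0.8, 5, 10, 12, 1, 150, 3, 7.5, 100, 45),
      default = c(0.5, 3, 6, 6, 0.21, 80, 1.5, 7.3, 70, 35),
      unit = c("L", "s", "s", "cmH2O", "-", "mL/cmH2O", "L/min", "-",
               "mmHg", "mmHg"),
      scale = c(1, 1, 1, 1, 1, 1e-3, 1 / 60, NA, 1, 1)
    ),
    data.frame(
      name = c("F_ds", "F_sh", "V_D", "V_A0", "R_aw"),
      group = "intrinsic",
      min = c(0, 0, 0.15, 1, 10),
      max = c(0.95, 0.95, 0.35, 2.5, 25),
      default = c(0.25, 0.25, 0.25, 1.5, 15),
      unit = c("-", "-", "L", "L", "cmH2O.s/L"),
      scale = 1
    ),
    data.frame(
      name = c("FiCO2", "P_atm", "P_w", "VdotO2", "VdotCO2", "DO2", "DCO2",
               "DO2p", "DCO2p", "sigmaO2", "sigmaCO2", "V_c_tot", "delta",
               "r2", "l2"),
      group = "constant",
      min = NA_real_,
      max = NA_real_,
      default = c(4.0e-4, 760, 47, 1.5e-4, 1.2e-4, 3.5e-4, 7.08e-4,
                  1.56e-5, 3.16e-5, 1.4e-6, 3.3e-5, 7.1e-2, 10^1.9, 0.12,
                  164e3),
      unit = c("-", "mmHg", "mmHg", "L/s", "L/s", "L/s/mmHg", "L/s/mmHg",
               "mol/s/mmHg", "mol/s/mmHg", "mol/L/mmHg", "mol/L/mmHg", "L",
               "-", "1/s", "L/mol/s"),
      scale = 1
    )
  )
  rownames(df) <- NULL
  df
}

#' Sensor accuracy of the clinically measured inputs
#'
#' Standard deviations of the monitored input channels, derived from the
#' reported accuracy of the EVLP monitor sensors. These define the input
#' distributions for Monte-Carlo uncertainty propagation. Units match the
#' canonical internal units except where noted: the flow accuracy is given
#' in L/s, the pH accuracy in pH units. Static compliance has no reported
#' sensor accuracy and is therefore not perturbed.
#'
#' @return Named numeric vector of standard deviations for `Vt` (L),
#'   `T_insp` (s), `T_exp` (s), `PEEP` (cmH2O), `FiO2` (-), `Q` (L/s),
#'   `pH` (-), `P_PA_O2` (mmHg), `P_PA_CO2` (mmHg).
#' @export
sensor_sds <- function() {
  c(Vt = 2.6e-2, T_insp = 5.1e-2, T_exp = 5.1e-2, PEEP = 1.0,
    FiO2 = 1.3e-2, Q = 8.5e-4, pH = 5.1e-2, P_PA_O2 = 5.1, P_PA_CO2 = 5.1)
}

#' Convert airway pressure from cmH2O to mmHg
#'
#' Airway-side pressures are carried in cmH2O, gas tensions in mmHg; this
#' conversion (1 cmH2O = 0.7356 mmHg) links the two when computing
#' alveolar partial pressures.
#'
#' @param p Pressure in cmH2O.
#' @return Pressure in mmHg.
#' @export
cmh2o_to_mmhg <- function(p) 0.7356 * p

#' @rdname cmh2o_to_mmhg
#' @export
mmhg_to_cmh2o <- function(p) p / 0.7356

.table_names <- function() evlp_ranges()$name

#' Build a model configuration
#'
#' Constructs a complete, canonically united model configuration starting
#' from the default parameter set, with any parameter overridden by name in
#' table units (`C_stat` in mL/cmH2O, `Q` in L/min, acidity as `pH`).
#'
#' @param ... Named overrides in table units, e.g. `F_sh = 0.5`, `Q = 3`.
#' @return An object of class `evlp_config`: a list with elements
#'   `clinical`, `intrinsic` and `constants` holding canonical values, e.g.
#'   `clinical$C_stat` in L/cmH2O and `clinical$Q` in L/s.
#' @examples
#' cfg <- default_config(F_sh = 0.35, Q = 3)
#' cfg$clinical$Q    # 0.05 L/s
#' @export
default_config <- function(...) {
  rng <- evlp_ranges()
  vals <- stats::setNames(rng$default, rng$name)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), rng$name)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    vals[names(ov)] <- unlist(ov)
  }
  canon <- vals
  sc <- stats::setNames(rng$scale, rng$name)
  conv <- !is.na(sc) & sc != 1
  canon[conv] <- canon[conv] * sc[conv]
  cfg <- list(
    clinical = as.list(canon[rng$name[rng$group == "clinical"]]),
    intrinsic = as.list(canon[rng$name[rng$group == "intrinsic"]]),
    constants = as.list(canon[rng$name[rng$group == "constant"]])
  )
  class(cfg) <- "evlp_config"
  cfg
}

#' Update a configuration
#'
#' Returns a copy of `config` with the named parameters replaced. Values
#' are given in table units, as for [default_config()].
#'
#' @param config An `evlp_config`.
#' @param ... Named overrides in table units.
#' @return The updated `evlp_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "evlp_config"))
  ov <- list(...)
  if (!length(ov)) return(config)
  rng <- evlp_ranges()
  bad <- setdiff(names(ov), rng$name)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    sc <- rng$scale[rng$name == nm]
    val <- ov[[nm]]
    if (!is.na(sc) && sc != 1) val <- val * sc
    grp <- rng$group[rng$name == nm]
    slot <- c(clinical = "clinical", intrinsic = "intrinsic",
              constant = "constants")[[grp]]
    config[[slot]][[nm]] <- val
  }
  config
}

#' Express a configuration in table units
#'
#' Inverse of the conversion applied by [default_config()]: canonical
#' values are mapped back to the user-facing units (mL/cmH2O, L/min, pH).
#'
#' @param config An `evlp_config`.
#' @return Named numeric vector in table units, ordered as [evlp_ranges()].
#' @export
as_table_units <- function(config) {
  stopifnot(inherits(config, "evlp_config"))
  rng <- evlp_ranges()
  vals <- unlist(c(config$clinical, config$intrinsic, config$constants))
  vals <- vals[rng$name]
  conv <- !is.na(rng$scale) & rng$scale != 1
  vals[conv] <- vals[conv] / rng$scale[conv]
  vals
}

#' Validate a configuration against its normal ranges
#'
#' Checks every clinical and intrinsic parameter against its normal range
#' (in table units), positivity of the constants, and the composite
#' requirement `F_ds + F_sh < 1` (the gas-exchange compartment must be
#' non-empty). Violations are returned as data, not raised.
#'
#' @param config An `evlp_config`.
#' @return A data.frame with columns `field`, `value`, `message`; zero rows
#'   when the configuration is valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "evlp_config"))
  rng <- evlp_ranges()
  vals <- as_table_units(config)
  out <- data.frame(field = character(), value = numeric(),
                    message = character())
  for (i in seq_len(nrow(rng))) {
    nm <- rng$name[i]
    v <- vals[[nm]]
    if (!is.finite(v)) {
      out <- rbind(out, data.frame(field = nm, value = v,
                                   message = "non-finite value"))
      next
    }
    if (rng$group[i] == "constant") {
      if (v <= 0)
        out <- rbind(out, data.frame(
          field = nm, value = v, message = "constant must be positive"))
      next
    }
    if (v < rng$min[i] - 1e-12)
      out <- rbind(out, data.frame(field = nm, value = v, message = sprintf(
        "%s < %g (normal range %g-%g %s)", nm, rng$min[i], rng$min[i],
        rng$max[i], rng$unit[i])))
    if (v > rng$max[i] + 1e-12)
      out <- rbind(out, data.frame(field = nm, value = v, message = sprintf(
        "%s > %g (normal range %g-%g %s)", nm, rng$max[i], rng$min[i],
        rng$max[i], rng$unit[i])))
  }
  fsum <- config$intrinsic$F_ds + config$intrinsic$F_sh
  if (is.finite(fsum) && fsum >= 1)
    out <- rbind(out, data.frame(
      field = "F_ds+F_sh", value = fsum,
      message = "F_ds + F_sh >= 1: gas-exchange compartment is empty"))
  rownames(out) <- NULL
  out
}

# Canonical 30-element parameter vector consumed by the compiled core.
# Order must match the layout documented in src/evlp_core.cpp.
config_to_pars <- function(config) {
  cl <- config$clinical
  it <- config$intrinsic
  ct <- config$constants
  c(cl$Vt, cl$T_insp, cl$T_exp, cl$PEEP, cl$FiO2, cl$C_stat, cl$Q,
    10^(-cl$pH), cl$P_PA_O2, cl$P_PA_CO2,
    it$F_ds, it$F_sh, it$V_D, it$V_A0, it$R_aw,
    ct$FiCO2, ct$P_atm, ct$P_w, ct$VdotO2, ct$VdotCO2, ct$DO2, ct$DCO2,
    ct$DO2p, ct$DCO2p, ct$sigmaO2, ct$sigmaCO2, ct$V_c_tot, ct$delta,
    ct$r2, ct$l2)
}

pars_names <- function() {
  c("Vt", "T_insp", "T_exp", "PEEP", "FiO2", "C_stat", "Q", "H",
    "P_PA_O2", "P_PA_CO2", "F_ds", "F_sh", "V_D", "V_A0", "R_aw",
    "FiCO2", "P_atm", "P_w", "VdotO2", "VdotCO2", "DO2", "DCO2", "DO2p",
    "DCO2p", "sigmaO2", "sigmaCO2", "V_c_tot", "delta", "r2", "l2")
}

#' Read or write a configuration as JSON
#'
#' The file mirrors the table-unit parameter names of [evlp_ranges()];
#' unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path File path.
#' @param config An `evlp_config` (for writing).
#' @return `read_config` returns an `evlp_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(vals)) return(default_config())
  bad <- setdiff(names(vals), .table_names())
  if (length(bad))
    stop("unknown key(s) in config file: ", paste(bad, collapse = ", "))
  do.call(default_config, as.list(vals))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  vals <- as.list(as_table_units(config))
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.evlp_config <- function(x, ...) {
  v <- as_table_units(x)
  rng <- evlp_ranges()
  cat("<evlp_config>\n")
  for (g in c("clinical", "intrinsic", "constant")) {
    cat(" ", g, ":\n", sep = "")
    nm <- rng$name[rng$group == g]
    cat(paste0("    ", format(nm, width = 10), " = ",
               signif(v[nm], 6), " ", rng$unit[rng$group == g],
               collapse = "\n"), "\n")
  }
  invisible(x)
}
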