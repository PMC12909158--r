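# Alveolar-capillary gas exchange of an acellular perfusate.
#
# These R functions are the reference transcription of the gas-exchange
# equations.  The compiled integrator re-implements the same expressions
# for speed; the test suite cross-checks the two implementations
# derivative-for-derivative on randomised states, so the R functions act
# as an independent oracle for the C++ core (and vice versa).

#' Alveolar partial pressures from gas fractions
#'
#' A gas fraction times the dry-gas pressure: the absolute alveolar
#' pressure (atmospheric plus the airway-gauge alveolar pressure) minus
#' water vapour pressure.
#'
#' @param F_A_O2,F_A_CO2 Alveolar gas fractions \[-\].
#' @param P_A Alveolar pressure \[cmH2O\], airway gauge.
#' @param constants List of physical constants (`config$constants`).
#' @return Named vector `c(P_A_O2, P_A_CO2)` \[mmHg\].
#' @examples
#' co <- default_config()$constants
#' alveolar_partial_pressures(0.18, 0.030, 0, co)  # 128.34, 21.39 mmHg
#' @export
alveolar_partial_pressures <- function(F_A_O2, F_A_CO2, P_A, constants) {
  Pdry <- constants$P_atm + cmh2o_to_mmhg(P_A) - constants$P_w
  c(P_A_O2 = F_A_O2 * Pdry, P_A_CO2 = F_A_CO2 * Pdry)
}

#' Mixed inspired gas fractions after the anatomical dead space
#'
#' During expiration the conducting airways (anatomical dead space `V_D`)
#' fill with end-expiratory alveolar gas, which is rebreathed at the next
#' inspiration. Two mixing models are provided:
#'
#' * `"dilution"` (default): the inspirate reaching the alveoli carries a
#'   constant volume-weighted mixture over the whole breath,
#'   `F_D = (F_endexp * min(V_D, Vt) + F_i * max(Vt - V_D, 0)) / Vt`.
#' * `"plug"`: a sharp front — rebreathed end-expiratory gas while the
#'   cumulative inspired volume is below `V_D`, pure fresh gas after.
#'
#' The dilution model is the package default; see the methods vignette for
#' why plug flow interacts badly with the ramp ventilator's delivered
#' volume.
#'
#' @param inspired_volume_so_far Cumulative inspired alveolar volume in the
#'   current breath \[L\] (used by the plug model).
#' @param V_D Anatomical dead-space volume \[L\].
#' @param FiO2,FiCO2 Set inspired gas fractions \[-\].
#' @param end_exp_F_A_O2,end_exp_F_A_CO2 Alveolar fractions frozen at the
#'   previous end-expiration \[-\].
#' @param Vt Set tidal volume \[L\] (dilution model weighting).
#' @param mixing `"dilution"` or `"plug"`.
#' @return Named vector `c(F_D_O2, F_D_CO2)`.
#' @export
mixed_inspired_fractions <- function(inspired_volume_so_far, V_D, FiO2,
                                     FiCO2, end_exp_F_A_O2,
                                     end_exp_F_A_CO2, Vt,
                                     mixing = c("dilution", "plug")) {
  mixing <- match.arg(mixing)
  if (inspired_volume_so_far < 0) stop("inspired volume must be >= 0")
  if (mixing == "plug") {
    if (V_D > 0 && inspired_volume_so_far < V_D)
      return(c(F_D_O2 = end_exp_F_A_O2, F_D_CO2 = end_exp_F_A_CO2))
    return(c(F_D_O2 = FiO2, F_D_CO2 = FiCO2))
  }
  w <- min(V_D, Vt) / Vt
  c(F_D_O2 = (1 - w) * FiO2 + w * end_exp_F_A_O2,
    F_D_CO2 = (1 - w) * FiCO2 + w * end_exp_F_A_CO2)
}

#' Alveolar gas-fraction derivatives
#'
#' Species balance on the gas-exchange volume: membrane diffusion,
#' inspiratory refreshment, normalisation by the total molar flux (a
#' change in total gas content dilutes or concentrates every species), and
#' lung metabolism (O2 consumption, CO2 production).
#'
#' @param state Named list/vector with `F_A_O2`, `F_A_CO2`, `P_c_O2`,
#'   `P_c_CO2`.
#' @param derived Named list with `P_A_O2`, `P_A_CO2` \[mmHg\], `F_D_O2`,
#'   `F_D_CO2` \[-\], `Vdot_A_ge_i` \[L/s\] (inspiratory flow into the
#'   gas-exchange volume, zero during expiration) and `V_A_ge` \[L\].
#' @param constants `config$constants`.
#' @return Named vector `c(dF_A_O2, dF_A_CO2)` \[1/s\].
#' @export
alveolar_fraction_derivs <- function(state, derived, constants) {
  if (derived$V_A_ge <= 0) stop("V_A_ge must be positive")
  jO2 <- constants$DO2 * (state[["P_c_O2"]] - derived$P_A_O2)
  jCO2 <- constants$DCO2 * (state[["P_c_CO2"]] - derived$P_A_CO2)
  FA_O2 <- state[["F_A_O2"]]
  FA_CO2 <- state[["F_A_CO2"]]
  vi <- derived$Vdot_A_ge_i
  dO2 <- (jO2 + (derived$F_D_O2 - FA_O2) * vi - FA_O2 * (jCO2 + jO2) +
            (FA_O2 - 1) * constants$VdotO2 - FA_O2 * constants$VdotCO2) /
    derived$V_A_ge
  dCO2 <- (jCO2 + (derived$F_D_CO2 - FA_CO2) * vi - FA_CO2 * (jCO2 + jO2) +
             (1 - FA_CO2) * constants$VdotCO2 + FA_CO2 * constants$VdotO2) /
    derived$V_A_ge
  c(dF_A_O2 = dO2, dF_A_CO2 = dCO2)
}

#' Capillary partial-pressure derivatives
#'
#' Fick diffusion across the alveolar-capillary membrane (molar capacities
#' `DO2p`, `DCO2p` converted to tension rates by solubility times the
#' perfused gas-exchanging capillary volume), perfusate refreshment at
#' flow `Q` over the total capillary volume, and — for CO2 — exchange with
#' the bicarbonate pool. The lumped single-compartment closure identifies
#' the end-capillary tensions with the compartment tensions.
#'
#' @param state Named list/vector with `P_c_O2`, `P_c_CO2`, `z`.
#' @param derived Named list with `P_A_O2`, `P_A_CO2` \[mmHg\] and `V_c_ge`
#'   \[L\] (perfused capillary volume, `(1 - F_sh) * V_c_tot`).
#' @param clinical `config$clinical` (uses `Q`, `pH`, `P_PA_O2`,
#'   `P_PA_CO2`).
#' @param constants `config$constants`.
#' @return Named vector `c(dP_c_O2, dP_c_CO2)` \[mmHg/s\].
#' @export
capillary_pressure_derivs <- function(state, derived, clinical, constants) {
  if (derived$V_c_ge <= 0) stop("V_c_ge must be positive")
  h <- 10^(-clinical$pH)
  dO2 <- constants$DO2p / (constants$sigmaO2 * derived$V_c_ge) *
    (derived$P_A_O2 - state[["P_c_O2"]]) +
    clinical$Q / constants$V_c_tot *
    (clinical$P_PA_O2 - state[["P_c_O2"]])
  dCO2 <- constants$DCO2p / (constants$sigmaCO2 * derived$V_c_ge) *
    (derived$P_A_CO2 - state[["P_c_CO2"]]) +
    clinical$Q / constants$V_c_tot *
    (clinical$P_PA_CO2 - state[["P_c_CO2"]]) +
    constants$delta * constants$l2 * h * state[["z"]] / constants$sigmaCO2 -
    constants$delta * constants$r2 * state[["P_c_CO2"]]
  c(dP_c_O2 = dO2, dP_c_CO2 = dCO2)
}

#' Bicarbonate pool derivative
#'
#' CO2 hydration/dehydration kinetics accelerated by carbonic anhydrase:
#' `dz/dt = delta * r2 * sigmaCO2 * P_c_CO2 - delta * l2 * h * z`. The
#' negative of this flux, converted from concentration to tension units by
#' `sigmaCO2`, appears in the capillary CO2 balance, so total CO2 is
#' conserved between the dissolved and bicarbonate pools.
#'
#' @param P_c_CO2 Capillary CO2 tension \[mmHg\].
#' @param h Hydrogen-ion concentration \[mol/L\].
#' @param z Bicarbonate concentration \[mol/L\].
#' @param constants `config$constants`.
#' @return dz/dt \[mol/L/s\].
#' @export
bicarbonate_deriv <- function(P_c_CO2, h, z, constants) {
  if (any(c(P_c_CO2, h, z) < 0)) stop("inputs must be non-negative")
  constants$delta * constants$r2 * constants$sigmaCO2 * P_c_CO2 -
    constants$delta * constants$l2 * h * z
}

#' Left-atrial mixing of shunted and end-capillary perfusate
#'
#' The perfusate flow splits linearly with the shunt fraction; the shunted
#' stream bypasses gas exchange and retains the pulmonary-artery tension:
#' `P_LA = F_sh * P_PA + (1 - F_sh) * P_c_end`.
#'
#' @param P_PA_gas Pulmonary-artery tension \[mmHg\].
#' @param P_c_end_gas End-capillary tension \[mmHg\].
#' @param F_sh Intrapulmonary shunt fraction \[-\].
#' @return Left-atrial tension \[mmHg\].
#' @examples
#' left_atrial_mixing(70, 130, 0.25)  # 115
#' @export
left_atrial_mixing <- function(P_PA_gas, P_c_end_gas, F_sh) {
  if (any(F_sh < 0) || any(F_sh > 1)) stop("F_sh must be in [0, 1]")
  P_PA_gas * F_sh + (1 - F_sh) * P_c_end_gas
}
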