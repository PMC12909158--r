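# Single-compartment lung mechanics: one resistive airway element in
# series with a linear elastic alveolar compartment.  Ex vivo there is no
# chest wall, pleural pressure or muscular effort, so the full equation of
# motion collapses to a first-order RC system.

#' Rate of change of alveolar pressure
#'
#' `dP_A/dt = (P_vent - P_A) / (R_aw * C_stat)`.
#'
#' @param P_vent Ventilator pressure \[cmH2O\].
#' @param P_A Alveolar pressure \[cmH2O\].
#' @param R_aw Airway resistance \[cmH2O.s/L\].
#' @param C_stat Static compliance \[L/cmH2O\].
#' @return Derivative \[cmH2O/s\].
#' @export
dPA_dt <- function(P_vent, P_A, R_aw, C_stat) {
  if (any(R_aw <= 0) || any(C_stat <= 0))
    stop("R_aw and C_stat must be positive")
  (P_vent - P_A) / (R_aw * C_stat)
}

#' Airflow through the conducting airways
#'
#' Laminar flow across the airway resistance:
#' `(P_vent - P_A) / R_aw`; positive into the lung.
#'
#' @inheritParams dPA_dt
#' @return Flow \[L/s\].
#' @export
airflow <- function(P_vent, P_A, R_aw) {
  if (any(R_aw <= 0)) stop("R_aw must be positive")
  (P_vent - P_A) / R_aw
}

#' Partition the alveolar volume into functional compartments
#'
#' The total alveolar volume `V_tot = V_A0 + V_A` is split into three
#' fixed-fraction compartments: alveolar dead space (`F_ds`, ventilated
#' but unperfused), intrapulmonary shunt (`F_sh`, perfused but
#' unventilated) and the gas-exchange volume (`1 - F_ds - F_sh`).
#'
#' @param V_A Tidal alveolar volume above the unstressed volume \[L\].
#' @param intrinsic List with `F_ds`, `F_sh`, `V_A0` (e.g.
#'   `config$intrinsic`).
#' @return Named numeric vector `c(V_A_ge, V_A_ds, V_A_sh)` \[L\].
#' @export
partition_volumes <- function(V_A, intrinsic) {
  F_ds <- intrinsic$F_ds
  F_sh <- intrinsic$F_sh
  V_tot <- intrinsic$V_A0 + V_A
  if (any(V_tot <= 0)) stop("total alveolar volume must be positive")
  if (F_ds + F_sh >= 1) stop("F_ds + F_sh must be < 1")
  c(V_A_ge = (1 - F_ds - F_sh) * V_tot,
    V_A_ds = F_ds * V_tot,
    V_A_sh = F_sh * V_tot)
}
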