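# Pressure-ramp ventilator driving the model.

#' Plateau pressure required to deliver a set tidal volume
#'
#' The ventilator links the set tidal volume and PEEP to the measured
#' static compliance: `P_plat = PEEP + Vt / C_stat`. Note that this is the
#' pressure required under quasi-static conditions; with a finite
#' `R_aw * C_stat` time constant relative to the inspiratory time the ramp
#' ventilator delivers less than `Vt` (see the methods vignette).
#'
#' @param PEEP Positive end-expiratory pressure \[cmH2O\].
#' @param Vt Set tidal volume \[L\].
#' @param C_stat Static compliance \[L/cmH2O\] (canonical units).
#' @return Plateau pressure \[cmH2O\].
#' @examples
#' plateau_pressure(6, 0.5, 0.080)  # 12.25
#' @export
plateau_pressure <- function(PEEP, Vt, C_stat) {
  if (any(C_stat <= 0)) stop("C_stat must be positive")
  PEEP + Vt / C_stat
}

#' Ventilator waveform descriptor
#'
#' @param config An `evlp_config`, or `NULL` to supply the fields directly.
#' @param PEEP,Vt,C_stat,T_insp,T_exp Waveform fields (canonical units),
#'   used when `config` is `NULL`.
#' @return A list of class `evlp_waveform` with `PEEP`, `P_plat`, `T_insp`,
#'   `T_exp`, `T_cyc`.
#' @export
ventilator_waveform <- function(config = NULL, PEEP, Vt, C_stat, T_insp,
                                T_exp) {
  if (!is.null(config)) {
    cl <- config$clinical
    PEEP <- cl$PEEP; Vt <- cl$Vt; C_stat <- cl$C_stat
    T_insp <- cl$T_insp; T_exp <- cl$T_exp
  }
  if (T_insp <= 0 || T_exp <= 0) stop("T_insp and T_exp must be positive")
  wf <- list(PEEP = PEEP, P_plat = plateau_pressure(PEEP, Vt, C_stat),
             T_insp = T_insp, T_exp = T_exp, T_cyc = T_insp + T_exp)
  class(wf) <- "evlp_waveform"
  wf
}

#' Ventilator pressure at a given time
#'
#' Within each cycle (phase time `u = t mod T_cyc`, `t = 0` at inspiration
#' onset) the pressure ramps linearly from PEEP to the plateau pressure
#' over `T_insp`, then drops instantaneously back to PEEP for `T_exp`.
#'
#' @param t Time(s) \[s\], vectorised.
#' @param wf An `evlp_waveform`.
#' @return Ventilator pressure(s) \[cmH2O\].
#' @export
vent_pressure_at <- function(t, wf) {
  stopifnot(inherits(wf, "evlp_waveform"))
  u <- t %% wf$T_cyc
  ifelse(u <= wf$T_insp,
         wf$PEEP + (wf$P_plat - wf$PEEP) * u / wf$T_insp,
         wf$PEEP)
}
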