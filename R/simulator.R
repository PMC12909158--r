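# Assembly and integration of the full eight-state system.
#
# Six physiological states (P_A, F_A_O2, F_A_CO2, P_c_O2, P_c_CO2, z) plus
# two auxiliary integrator states: the tidal alveolar volume V_A and the
# cumulative inspired volume V_insp of the current breath (needed for the
# plug-flow dead-space front).  Integration uses an adaptive embedded
# Runge-Kutta pair at tolerance 1e-9 with maximal step 0.1 s, restarted at
# every ventilator phase discontinuity.

.state_names <- c("P_A", "F_A_O2", "F_A_CO2", "P_c_O2", "P_c_CO2", "z",
                  "V_A", "V_insp")

#' Initial state vector
#'
#' Default initial values of the physiological states; the auxiliary
#' states start at zero (the tidal volume is referenced to the lung volume
#' at the initial alveolar pressure).
#'
#' @param config Unused except for interface symmetry; initial values are
#'   configuration-independent.
#' @return Named numeric vector of the eight integrator states.
#' @export
initial_state <- function(config = default_config()) {
  c(P_A = 7, F_A_O2 = 0.18, F_A_CO2 = 0.030, P_c_O2 = 125, P_c_CO2 = 25,
    z = 1.7e-2, V_A = 0, V_insp = 0)
}

#' Full model right-hand side (reference implementation)
#'
#' Composes the ventilator, mechanics and gas-exchange operations into the
#' complete state derivative, entirely in R. The compiled integrator used
#' by [simulate_evlp()] implements the same system; the two are
#' cross-checked in the test suite.
#'
#' @param t Time \[s\] (`t = 0` at an inspiration onset).
#' @param state Named state vector as returned by [initial_state()].
#' @param config An `evlp_config`.
#' @param fd Dead-space gas composition frozen at the current inspiration
#'   onset, `c(F_A_O2, F_A_CO2)`.
#' @param mixing Dead-space mixing model, `"dilution"` (default) or
#'   `"plug"`.
#' @return Named derivative vector (same layout as `state`).
#' @export
evlp_rhs <- function(t, state, config, fd = state[c("F_A_O2", "F_A_CO2")],
                     mixing = c("dilution", "plug")) {
  mixing <- match.arg(mixing)
  cl <- config$clinical
  it <- config$intrinsic
  ct <- config$constants
  wf <- ventilator_waveform(config)
  u <- t %% wf$T_cyc
  insp <- u < wf$T_insp - 1e-12 || u < 1e-12
  pvent <- if (insp) wf$PEEP + (wf$P_plat - wf$PEEP) * u / wf$T_insp
           else wf$PEEP
  flow <- airflow(pvent, state[["P_A"]], it$R_aw)
  vols <- partition_volumes(state[["V_A"]], it)
  pp <- alveolar_partial_pressures(state[["F_A_O2"]], state[["F_A_CO2"]],
                                   state[["P_A"]], ct)
  fin <- if (insp && flow > 0) flow else 0
  vi <- fin * vols[["V_A_ge"]] / (vols[["V_A_ge"]] + vols[["V_A_ds"]])
  if (insp) {
    fdm <- mixed_inspired_fractions(state[["V_insp"]], it$V_D, cl$FiO2,
                                    ct$FiCO2, fd[[1]], fd[[2]], cl$Vt,
                                    mixing)
  } else {
    fdm <- c(F_D_O2 = cl$FiO2, F_D_CO2 = ct$FiCO2)
  }
  derived <- list(P_A_O2 = pp[["P_A_O2"]], P_A_CO2 = pp[["P_A_CO2"]],
                  F_D_O2 = fdm[["F_D_O2"]], F_D_CO2 = fdm[["F_D_CO2"]],
                  Vdot_A_ge_i = vi, V_A_ge = vols[["V_A_ge"]],
                  V_c_ge = (1 - it$F_sh) * ct$V_c_tot)
  dfa <- alveolar_fraction_derivs(state, derived, ct)
  dpc <- capillary_pressure_derivs(state, derived, cl, ct)
  dz <- bicarbonate_deriv(state[["P_c_CO2"]], 10^(-cl$pH), state[["z"]],
                          ct)
  out <- c(dPA_dt(pvent, state[["P_A"]], it$R_aw, cl$C_stat),
           dfa[["dF_A_O2"]], dfa[["dF_A_CO2"]],
           dpc[["dP_c_O2"]], dpc[["dP_c_CO2"]], dz, flow, fin)
  names(out) <- .state_names
  if (any(!is.finite(out)))
    stop("non-finite derivative at t = ", t, "; state: ",
         paste(signif(state, 4), collapse = ", "))
  out
}

#' Piecewise-constant input schedule
#'
#' Describes step changes of clinically measured inputs during a
#' simulation, e.g. the inspired oxygen fraction stepping to 100 % during
#' an oxygenation challenge. Values are in table units (as for
#' [update_config()]).
#'
#' @param time Change times \[s\], non-decreasing.
#' @param param Parameter names (clinical inputs).
#' @param value New values (table units).
#' @return A data.frame of class `evlp_schedule`.
#' @export
input_schedule <- function(time, param, value) {
  stopifnot(length(time) == length(param), length(time) == length(value))
  if (is.unsorted(time)) stop("schedule times must be non-decreasing")
  rng <- evlp_ranges()
  bad <- setdiff(param, rng$name[rng$group == "clinical"])
  if (length(bad))
    stop("schedule may only change clinical inputs; offending: ",
         paste(bad, collapse = ", "))
  out <- data.frame(time = time, param = param, value = value)
  class(out) <- c("evlp_schedule", "data.frame")
  out
}

#' Oxygenation-challenge schedule
#'
#' @param step_time Time of the FiO2 step \[s\].
#' @param fio2 Post-step inspired oxygen fraction.
#' @return An `evlp_schedule` with a single FiO2 step.
#' @export
fio2_challenge_schedule <- function(step_time = 180, fio2 = 1.0) {
  input_schedule(step_time, "FiO2", fio2)
}

#' Simulate the model
#'
#' Integrates the full system over `[t0, t0 + duration]` with adaptive
#' error control (absolute and relative tolerance `1e-9`, maximal step
#' 0.1 s), restarting at each ventilator phase discontinuity, and samples
#' the solution on a uniform output grid (100 Hz by default).
#'
#' @param config An `evlp_config`.
#' @param duration Simulated duration \[s\].
#' @param schedule Optional `evlp_schedule` of input steps (times relative
#'   to the same origin as `t0`).
#' @param init Initial state (named vector, see [initial_state()]).
#' @param dt_out Output sampling interval \[s\]; 0.01 gives the 100 Hz
#'   grid.
#' @param t0 Start time \[s\]; `t = 0` is an inspiration onset.
#' @param rtol,atol,hmax Solver settings.
#' @param mixing Dead-space mixing model (see
#'   [mixed_inspired_fractions()]).
#' @param fd0 Dead-space composition carried in when resuming mid-breath;
#'   default: alveolar fractions of `init`.
#' @return An object of class `evlp_sim`: list with `time`, `states`
#'   (matrix, one column per state), `P_LA_O2`, `P_LA_CO2`, `config`,
#'   `final_state`, `fd_final`.
#' @export
simulate_evlp <- function(config, duration, schedule = NULL,
                          init = initial_state(config), dt_out = 0.01,
                          t0 = 0, rtol = 1e-9, atol = 1e-9, hmax = 0.1,
                          mixing = c("dilution", "plug"), fd0 = NULL) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(config, "evlp_config"), duration > 0)
  mix <- if (mixing == "plug") 1L else 0L
  t1 <- t0 + duration
  sample_times <- seq(t0, t1, by = dt_out)
  if (is.null(fd0)) fd0 <- unname(init[c("F_A_O2", "F_A_CO2")])

  chg <- if (is.null(schedule)) numeric(0) else
    sort(unique(schedule$time[schedule$time > t0 & schedule$time < t1]))
  bounds <- c(t0, chg, t1)
  y <- unname(init[.state_names])
  fd <- fd0
  cfg <- config
  times <- numeric(0)
  states <- NULL
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    if (!is.null(schedule)) {
      act <- schedule[schedule$time <= a + 1e-9, , drop = FALSE]
      if (nrow(act)) {
        # last value wins per parameter
        for (p in unique(act$param)) {
          v <- act$value[act$param == p]
          cfg <- do.call(update_config,
                         c(list(config), stats::setNames(list(v[length(v)]),
                                                         p)))
          config <- cfg
        }
      }
    }
    st <- sample_times[sample_times >= a - 1e-9 & sample_times <= b + 1e-9]
    res <- cpp_simulate(config_to_pars(cfg), y, fd, a, b, st, rtol, atol,
                        hmax, mix)
    keep <- if (length(times)) res$time > times[length(times)] + 1e-9 else
      rep(TRUE, length(res$time))
    times <- c(times, res$time[keep])
    states <- rbind(states, res$states[keep, , drop = FALSE])
    y <- res$y_end
    fd <- res$fd_end
  }
  colnames(states) <- .state_names
  it <- config$intrinsic
  cl <- config$clinical
  out <- list(
    time = times,
    states = states,
    P_LA_O2 = left_atrial_mixing(cl$P_PA_O2, states[, "P_c_O2"], it$F_sh),
    P_LA_CO2 = left_atrial_mixing(cl$P_PA_CO2, states[, "P_c_CO2"],
                                  it$F_sh),
    config = config,
    final_state = stats::setNames(y, .state_names),
    fd_final = fd,
    dt_out = dt_out
  )
  class(out) <- "evlp_sim"
  out
}

#' @export
print.evlp_sim <- function(x, ...) {
  cat(sprintf(
    "<evlp_sim> %d samples over %.2f s (dt = %g s)\n", length(x$time),
    diff(range(x$time)), x$dt_out))
  cat(sprintf("  P_LA_O2:  %.1f-%.1f mmHg\n", min(x$P_LA_O2),
              max(x$P_LA_O2)))
  cat(sprintf("  P_LA_CO2: %.1f-%.1f mmHg\n", min(x$P_LA_CO2),
              max(x$P_LA_CO2)))
  invisible(x)
}

#' Integrate to cyclic steady state
#'
#' Runs whole ventilator cycles until the cycle means of both left-atrial
#' tensions change by less than `tol` between successive cycles (default
#' 0.05 mmHg, an order of magnitude below the sensor accuracy), capped at
#' `max_time` of simulated time.
#'
#' @inheritParams simulate_evlp
#' @param tol Convergence tolerance on successive cycle means \[mmHg\].
#' @param max_time Cap on simulated time \[s\].
#' @param error_on_fail Raise an error when the cap is reached without
#'   convergence (default); otherwise return with `converged = FALSE`.
#' @return List with `state` (end-of-cycle state vector), `fd`, `P_LA_O2`
#'   and `P_LA_CO2` (converged cycle means \[mmHg\]), `cycle_means`
#'   (data.frame of per-cycle means), `n_cycles`, `converged`.
#' @export
run_to_steady_state <- function(config, init = initial_state(config),
                                tol = 0.05, max_time = 600, rtol = 1e-9,
                                atol = 1e-9, hmax = 0.1,
                                mixing = c("dilution", "plug"),
                                error_on_fail = TRUE) {
  mixing <- match.arg(mixing)
  mix <- if (mixing == "plug") 1L else 0L
  fd0 <- unname(init[c("F_A_O2", "F_A_CO2")])
  res <- cpp_run_to_steady(config_to_pars(config),
                           unname(init[.state_names]), fd0, tol, max_time,
                           rtol, atol, hmax, mix)
  if (!res$converged && error_on_fail)
    stop(sprintf(
      "no cyclic steady state within %.0f s (%d cycles; last cycle-mean drift %.3g mmHg)",
      max_time, res$n_cycles,
      max(abs(diff(utils::tail(res$mean_pla_o2, 2))),
          abs(diff(utils::tail(res$mean_pla_co2, 2))))))
  list(state = stats::setNames(res$y_end, .state_names),
       fd = res$fd_end,
       P_LA_O2 = res$mean_pla_o2[res$n_cycles],
       P_LA_CO2 = res$mean_pla_co2[res$n_cycles],
       cycle_means = data.frame(cycle = seq_len(res$n_cycles),
                                P_LA_O2 = res$mean_pla_o2,
                                P_LA_CO2 = res$mean_pla_co2),
       n_cycles = res$n_cycles,
       converged = res$converged)
}

#' Cycle-resolved static scenarios
#'
#' The four canonical static scenarios: baseline dead-space and shunt
#' fractions (25 %/25 %), increased dead space (50 %/25 %), increased
#' shunt (25 %/50 %), and doubled perfusate flow (3 L/min at 25 %/25 %).
#' Each runs to steady state and is then simulated for a 30-s window.
#'
#' @param config Base configuration.
#' @param window Simulated window after steady state \[s\].
#' @param ... Passed to [run_to_steady_state()] and [simulate_evlp()].
#' @return A data.frame with one row per scenario: `F_ds`, `F_sh`,
#'   `Q_l_min`, and mean/min/max of both left-atrial tensions over the
#'   window.
#' @export
run_static_scenarios <- function(config = default_config(), window = 30,
                                 ...) {
  scen <- data.frame(
    scenario = c("baseline", "high_deadspace", "high_shunt",
                 "double_flow"),
    F_ds = c(0.25, 0.50, 0.25, 0.25),
    F_sh = c(0.25, 0.25, 0.50, 0.25),
    Q_l_min = c(1.5, 1.5, 1.5, 3.0))
  rows <- lapply(seq_len(nrow(scen)), function(i) {
    cfg <- update_config(config, F_ds = scen$F_ds[i], F_sh = scen$F_sh[i],
                         Q = scen$Q_l_min[i])
    ss <- run_to_steady_state(cfg, ...)
    sim <- simulate_evlp(cfg, duration = window, init = ss$state,
                         fd0 = ss$fd, ...)
    data.frame(mean_P_LA_O2 = mean(sim$P_LA_O2),
               min_P_LA_O2 = min(sim$P_LA_O2),
               max_P_LA_O2 = max(sim$P_LA_O2),
               mean_P_LA_CO2 = mean(sim$P_LA_CO2),
               min_P_LA_CO2 = min(sim$P_LA_CO2),
               max_P_LA_CO2 = max(sim$P_LA_CO2))
  })
  cbind(scen, do.call(rbind, rows))
}

#' Nearest-neighbour resampling onto a coarser grid
#'
#' Matches each target time to the closest simulated sample, breaking
#' exact ties toward the earlier index (the convention used when
#' comparing simulations with a 3-s monitor record).
#'
#' @param x An `evlp_sim`, or a numeric vector of grid times.
#' @param target_times Times to resample at \[s\]; must lie within the
#'   simulated span.
#' @param values When `x` is a numeric grid: the values on that grid.
#' @return For an `evlp_sim`: data.frame with `time`, `P_LA_O2`,
#'   `P_LA_CO2`; otherwise the resampled `values`.
#' @export
resample_nearest <- function(x, target_times, values = NULL) {
  grid <- if (inherits(x, "evlp_sim")) x$time else x
  if (any(target_times < grid[1] - 1e-9) ||
      any(target_times > grid[length(grid)] + 1e-9))
    stop("target times outside the simulated span")
  idx <- findInterval(target_times, grid, all.inside = TRUE)
  d_lo <- target_times - grid[idx]
  d_hi <- grid[pmin(idx + 1, length(grid))] - target_times
  use_hi <- d_hi < d_lo - 1e-12 # strict: ties go to the earlier index
  idx[use_hi] <- idx[use_hi] + 1
  if (inherits(x, "evlp_sim"))
    data.frame(time = target_times, P_LA_O2 = x$P_LA_O2[idx],
               P_LA_CO2 = x$P_LA_CO2[idx])
  else values[idx]
}

#' Steady state followed by an oxygenation challenge
#'
#' Convenience driver used by the sensitivity study, record generation and
#' calibration: run to cyclic steady state at the pre-step FiO2, then
#' simulate an epoch in which FiO2 steps to `post_fio2` at `step_time`.
#'
#' @param config Configuration; its FiO2 is overridden by `pre_fio2`.
#' @param pre_fio2,post_fio2 Inspired O2 fraction before/after the step.
#' @param step_time Step time within the epoch \[s\].
#' @param duration Epoch length \[s\].
#' @param dt_out Output sampling interval \[s\].
#' @param ... Passed to [run_to_steady_state()]/[simulate_evlp()].
#' @return The `evlp_sim` for the epoch, with attributes `baseline`
#'   (pre-step steady cycle-mean P_LA_O2 \[mmHg\]), `baseline_co2`, and
#'   `step_time`.
#' @export
run_challenge <- function(config, pre_fio2 = 0.21, post_fio2 = 1.0,
                          step_time = 180, duration = 900, dt_out = 0.01,
                          ...) {
  cfg <- update_config(config, FiO2 = pre_fio2)
  ss <- run_to_steady_state(cfg, ...)
  sim <- simulate_evlp(cfg, duration = duration,
                       schedule = fio2_challenge_schedule(step_time,
                                                          post_fio2),
                       init = ss$state, fd0 = ss$fd, dt_out = dt_out, ...)
  attr(sim, "baseline") <- ss$P_LA_O2
  attr(sim, "baseline_co2") <- ss$P_LA_CO2
  attr(sim, "step_time") <- step_time
  sim
}
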