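# Shared fixtures and helpers for the test suite.  Everything is built in
# code at test time; no stored data.

default_cfg <- default_config()

# The clinically calibrated intrinsic parameter set (donor-lung example).
calibrated_cfg <- default_config(R_aw = 20, V_D = 0.29, F_ds = 0.30,
                                 F_sh = 0.35)

# A fast-mechanics configuration in the regime R_aw * C_stat << T_insp,
# where the ramp ventilator actually delivers the set tidal volume.
fast_mech_cfg <- default_config(Vt = 0.3, C_stat = 20, R_aw = 10,
                                T_insp = 5, T_exp = 10)

# Random valid state vectors for property tests (named, model units).
random_states <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c(P_A = runif(1, 5, 20),
      F_A_O2 = runif(1, 0.05, 0.9),
      F_A_CO2 = runif(1, 0.001, 0.08),
      P_c_O2 = runif(1, 40, 600),
      P_c_CO2 = runif(1, 10, 60),
      z = runif(1, 0.005, 0.03),
      V_A = runif(1, -0.2, 0.6),
      V_insp = runif(1, 0, 0.5))
  })
}

# Random valid configurations for property tests.
random_configs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      fds <- runif(1, 0, 0.6)
      fsh <- runif(1, 0, 0.6)
      if (fds + fsh < 0.9) break
    }
    default_config(
      Vt = runif(1, 0.2, 0.8), T_insp = runif(1, 1, 5),
      T_exp = runif(1, 2, 10), PEEP = runif(1, 5, 12),
      FiO2 = runif(1, 0.21, 1), C_stat = runif(1, 20, 150),
      Q = runif(1, 0.5, 3), pH = runif(1, 7, 7.5),
      P_PA_O2 = runif(1, 40, 100), P_PA_CO2 = runif(1, 20, 45),
      F_ds = fds, F_sh = fsh, V_D = runif(1, 0.15, 0.35),
      V_A0 = runif(1, 1, 2.5), R_aw = runif(1, 10, 25))
  })
}

cycle_mean_pla <- function(sim, from = NULL, to = NULL) {
  keep <- rep(TRUE, length(sim$time))
  if (!is.null(from)) keep <- keep & sim$time >= from
  if (!is.null(to)) keep <- keep & sim$time <= to
  c(P_LA_O2 = mean(sim$P_LA_O2[keep]), P_LA_CO2 = mean(sim$P_LA_CO2[keep]))
}
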