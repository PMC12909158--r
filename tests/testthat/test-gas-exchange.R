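co <- default_cfg$constants

test_that("alveolar partial pressures are fraction times dry-gas pressure", {
  pp <- alveolar_partial_pressures(0.18, 0.030, 0, co)
  expect_equal(pp[["P_A_O2"]], 0.18 * (760 - 47))   # 128.34 mmHg
  expect_equal(pp[["P_A_CO2"]], 0.030 * (760 - 47)) # 21.39 mmHg
  expect_equal(alveolar_partial_pressures(0, 0.03, 5, co)[["P_A_O2"]], 0)
  # airway pressure enters through the cmH2O -> mmHg conversion
  pp2 <- alveolar_partial_pressures(0.18, 0.030, 10, co)
  expect_equal(pp2[["P_A_O2"]] - pp[["P_A_O2"]], 0.18 * 7.356,
               tolerance = 1e-9)
})

test_that("dead-space mixing: plug-flow front and dilution weighting", {
  # no dead space: always fresh gas, both models
  for (m in c("plug", "dilution"))
    expect_equal(
      unname(mixed_inspired_fractions(0, 0, 0.21, 4e-4, 0.17, 0.05, 0.5,
                                      m)),
      c(0.21, 4e-4))
  # plug flow: rebreathed before the front, fresh after
  expect_equal(
    unname(mixed_inspired_fractions(0.1, 0.25, 0.21, 4e-4, 0.17, 0.05,
                                    0.5, "plug")),
    c(0.17, 0.05))
  expect_equal(
    unname(mixed_inspired_fractions(0.3, 0.25, 0.21, 4e-4, 0.17, 0.05,
                                    0.5, "plug")),
    c(0.21, 4e-4))
  # dilution: volume-weighted mix, constant in inspired volume
  fd <- mixed_inspired_fractions(0.1, 0.25, 0.21, 4e-4, 0.17, 0.05, 0.5)
  expect_equal(fd[["F_D_O2"]], 0.5 * 0.21 + 0.5 * 0.17)
  expect_equal(fd,
               mixed_inspired_fractions(0.4, 0.25, 0.21, 4e-4, 0.17, 0.05,
                                        0.5))
  # dead space >= tidal volume: pure rebreathing
  fd2 <- mixed_inspired_fractions(0, 0.35, 0.21, 4e-4, 0.17, 0.05, 0.3)
  expect_equal(unname(fd2), c(0.17, 0.05))
})

test_that("alveolar fraction derivatives vanish at full equilibrium and
           respond to metabolism with the right signs", {
  state <- c(F_A_O2 = 0.18, F_A_CO2 = 0.03, P_c_O2 = 128.34,
             P_c_CO2 = 21.39)
  derived <- list(P_A_O2 = 128.34, P_A_CO2 = 21.39, F_D_O2 = 0.18,
                  F_D_CO2 = 0.03, Vdot_A_ge_i = 0.1, V_A_ge = 1)
  co0 <- co
  co0$VdotO2 <- 0
  co0$VdotCO2 <- 0
  expect_equal(unname(alveolar_fraction_derivs(state, derived, co0)),
               c(0, 0))
  # metabolism only: O2 falls, CO2 rises
  derived0 <- derived
  derived0$Vdot_A_ge_i <- 0
  d <- alveolar_fraction_derivs(state, derived0, co)
  expect_lt(d[["dF_A_O2"]], 0)
  expect_gt(d[["dF_A_CO2"]], 0)
})

test_that("capillary derivatives: equilibria, rate constant, buffering", {
  cl <- default_cfg$clinical
  derived <- list(P_A_O2 = 70, P_A_CO2 = 35,
                  V_c_ge = 0.75 * co$V_c_tot)
  st <- c(P_c_O2 = 70, P_c_CO2 = 35,
          z = co$r2 * co$sigmaCO2 * 35 / (co$l2 * 10^-7.3))
  d <- capillary_pressure_derivs(st, derived, cl, co)
  expect_equal(d[["dP_c_O2"]], 0, tolerance = 1e-10)
  expect_equal(d[["dP_c_CO2"]], 0, tolerance = 1e-8)
  # O2 diffusion rate constant at defaults (F_sh = 0.25)
  expect_equal(co$DO2p / (co$sigmaO2 * 0.75 * co$V_c_tot), 209.25553,
               tolerance = 1e-7)
})

test_that("bicarbonate kinetics match hand-evaluated reference values", {
  # delta*r2*sigmaCO2*P = 7.8638495e-3, delta*l2*h*z = 1.1099228e-2
  expect_equal(bicarbonate_deriv(25, 10^-7.3, 1.7e-2, co), -3.2353784e-3,
               tolerance = 1e-6)
  z_eq <- co$r2 * co$sigmaCO2 * 25 / (co$l2 * 10^-7.3)
  expect_equal(bicarbonate_deriv(25, 10^-7.3, z_eq, co), 0,
               tolerance = 1e-12)
  # doubling h doubles only the consumption term
  d1 <- bicarbonate_deriv(25, 1e-7, 1.7e-2, co)
  d2 <- bicarbonate_deriv(25, 2e-7, 1.7e-2, co)
  expect_equal(d2 - d1, -co$delta * co$l2 * 1e-7 * 1.7e-2,
               tolerance = 1e-9)
})

test_that("left-atrial mixing is the shunt-weighted average", {
  expect_equal(left_atrial_mixing(70, 130, 0.25), 115)
  expect_equal(left_atrial_mixing(70, 130, 0), 130)
  expect_equal(left_atrial_mixing(70, 130, 1), 70)
  expect_error(left_atrial_mixing(70, 130, 1.2), "F_sh")
})

test_that("flux balance: O2/CO2 molar flux leaving the alveoli equals the
           flux entering the capillary compartment", {
  cl <- default_cfg$clinical
  it <- default_cfg$intrinsic
  for (st in random_states(20, seed = 42)) {
    pp <- alveolar_partial_pressures(st[["F_A_O2"]], st[["F_A_CO2"]],
                                     st[["P_A"]], co)
    V_c_ge <- (1 - it$F_sh) * co$V_c_tot
    derived <- list(P_A_O2 = pp[["P_A_O2"]], P_A_CO2 = pp[["P_A_CO2"]],
                    V_c_ge = V_c_ge)
    d <- capillary_pressure_derivs(st, derived, cl, co)
    # capillary-side molar fluxes, with refreshment/buffering removed
    refresh_o2 <- cl$Q / co$V_c_tot * (cl$P_PA_O2 - st[["P_c_O2"]])
    refresh_co2 <- cl$Q / co$V_c_tot * (cl$P_PA_CO2 - st[["P_c_CO2"]])
    buff <- co$delta * co$l2 * 10^(-cl$pH) * st[["z"]] / co$sigmaCO2 -
      co$delta * co$r2 * st[["P_c_CO2"]]
    molar_in_o2 <- co$sigmaO2 * V_c_ge * (d[["dP_c_O2"]] - refresh_o2)
    molar_in_co2 <- co$sigmaCO2 * V_c_ge *
      (d[["dP_c_CO2"]] - refresh_co2 - buff)
    # alveolar-side molar flux: volumetric diffusion times molar density
    molar_out_o2 <- co$DO2 * (pp[["P_A_O2"]] - st[["P_c_O2"]]) *
      (co$DO2p / co$DO2)
    molar_out_co2 <- co$DCO2 * (pp[["P_A_CO2"]] - st[["P_c_CO2"]]) *
      (co$DCO2p / co$DCO2)
    expect_equal(molar_in_o2, molar_out_o2, tolerance = 1e-9)
    expect_equal(molar_in_co2, molar_out_co2, tolerance = 1e-9)
  }
})

test_that("compiled derivative matches the R transcription everywhere", {
  cfgs <- random_configs(5, seed = 3)
  states <- random_states(5, seed = 4)
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    st <- states[[i]]
    pv <- evlpsim:::config_to_pars(cfg)
    fd <- c(st[["F_A_O2"]] * 0.9, st[["F_A_CO2"]] * 1.1)
    tc <- cfg$clinical$T_insp + cfg$clinical$T_exp
    for (tt in c(0, 0.4 * cfg$clinical$T_insp,
                 cfg$clinical$T_insp + 0.5 * cfg$clinical$T_exp,
                 tc + 0.7 * cfg$clinical$T_insp)) {
      for (mix in c("dilution", "plug")) {
        mixi <- if (mix == "plug") 1L else 0L
        dR <- evlp_rhs(tt, st, cfg, fd = fd, mixing = mix)
        dC <- evlpsim:::cpp_rhs(tt, as.numeric(st), pv, fd, mixi)
        expect_equal(unname(dR), as.numeric(dC), tolerance = 1e-12)
      }
    }
  }
})
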