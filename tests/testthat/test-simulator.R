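test_that("rhs is pure, cycle-periodic, and matches finite differences", {
  st <- initial_state()
  d0 <- evlp_rhs(1.0, st, default_cfg)
  tc <- default_cfg$clinical$T_insp + default_cfg$clinical$T_exp
  expect_equal(evlp_rhs(1.0 + 3 * tc, st, default_cfg), d0)
  # explicit-Euler step agrees with the integrated trajectory to O(h)
  sim <- simulate_evlp(default_cfg, duration = 1, dt_out = 0.001)
  i <- 500
  stv <- sim$states[i, ]
  d <- evlp_rhs(sim$time[i], stv, default_cfg,
                fd = unname(sim$states[1, c("F_A_O2", "F_A_CO2")]))
  fd_num <- (sim$states[i + 1, ] - sim$states[i - 1, ]) / 0.002
  expect_equal(unname(d[c("P_A", "F_A_O2", "P_c_O2")]),
               unname(fd_num[c("P_A", "F_A_O2", "P_c_O2")]),
               tolerance = 1e-3)
})

test_that("equilibrium states give a zero derivative vector", {
  cfg <- default_cfg
  co <- cfg$constants
  cl <- cfg$clinical
  # build an exact equilibrium: mechanics at P_vent(t)=PEEP (expiration),
  # gases at capillary/alveolar/inspired equality, no metabolism
  cfg0 <- cfg
  cfg0$constants$VdotO2 <- 0
  cfg0$constants$VdotCO2 <- 0
  Pdry <- co$P_atm + cmh2o_to_mmhg(cl$PEEP) - co$P_w
  fo2 <- cl$FiO2
  fco2 <- co$FiCO2
  z_eq <- co$r2 * co$sigmaCO2 * (fco2 * Pdry) / (co$l2 * 10^(-cl$pH))
  cfg0$clinical$P_PA_O2 <- fo2 * Pdry
  cfg0$clinical$P_PA_CO2 <- fco2 * Pdry
  st <- c(P_A = cl$PEEP, F_A_O2 = fo2, F_A_CO2 = fco2,
          P_c_O2 = fo2 * Pdry, P_c_CO2 = fco2 * Pdry, z = z_eq, V_A = 0,
          V_insp = 1)
  d <- evlp_rhs(cl$T_insp + 1, st, cfg0, fd = c(fo2, fco2))
  expect_equal(max(abs(d)), 0, tolerance = 1e-10)
})

test_that("simulation oscillates with the ventilator: left-atrial PO2
           rises during inspiration and falls during expiration", {
  ss <- run_to_steady_state(default_cfg)
  sim <- simulate_evlp(default_cfg, duration = 30, init = ss$state,
                       fd0 = ss$fd)
  tc <- 9
  # compare the O2 extremes within one steady cycle
  cyc <- sim$time >= 9 & sim$time <= 18
  tmax <- sim$time[cyc][which.max(sim$P_LA_O2[cyc])]
  tmin <- sim$time[cyc][which.min(sim$P_LA_O2[cyc])]
  u_max <- tmax %% tc
  expect_gt(max(sim$P_LA_O2[cyc]) - min(sim$P_LA_O2[cyc]), 0.1)
  # the peak sits at/just after end-inspiration, the trough near
  # end-expiration
  expect_lt(u_max, 4.5)
  u_min <- tmin %% tc
  expect_true(u_min > 4.5 || u_min < 1.5) # trough around end-expiration
  # CO2 moves in antiphase
  expect_lt(cor(sim$P_LA_O2[cyc], sim$P_LA_CO2[cyc]), -0.5)
})

test_that("with a dominant shunt the left-atrial PO2 collapses onto the
           mixing identity", {
  cfg <- default_config(F_sh = 0.95, F_ds = 0.04)
  ss <- run_to_steady_state(cfg)
  sim <- simulate_evlp(cfg, duration = 9, init = ss$state, fd0 = ss$fd)
  pc <- mean(sim$states[, "P_c_O2"])
  expect_lt(abs(mean(sim$P_LA_O2) - (0.95 * 70 + 0.05 * pc)), 5)
})

test_that("solution is converged in tolerance and solver", {
  ss <- run_to_steady_state(default_cfg)
  sim1 <- simulate_evlp(default_cfg, duration = 9, init = ss$state,
                        fd0 = ss$fd)
  # halving the tolerance moves the cycle mean by < 0.01 mmHg
  sim2 <- simulate_evlp(default_cfg, duration = 9, init = ss$state,
                        fd0 = ss$fd, rtol = 5e-10, atol = 5e-10)
  expect_lt(abs(mean(sim1$P_LA_O2) - mean(sim2$P_LA_O2)), 0.01)
  # fixed-step RK4 reference at dt = 1e-4 agrees to < 0.1 mmHg
  pv <- evlpsim:::config_to_pars(default_cfg)
  ref <- evlpsim:::cpp_simulate_fixed(pv, unname(ss$state), ss$fd, 0, 9,
                                      1e-4, seq(0, 9, by = 0.01), 0L)
  pla_ref <- 70 * 0.25 + 0.75 * ref$states[, 4]
  expect_lt(abs(mean(sim1$P_LA_O2) - mean(pla_ref)), 0.1)
  expect_lt(max(abs(sim1$P_LA_O2 - pla_ref)), 0.1)
})

test_that("the stiff-regime tableau satisfies the order-4 conditions and
           is L-stable", {
  A <- matrix(0, 5, 5)
  A[1, 1] <- 1 / 4
  A[2, 1:2] <- c(1 / 2, 1 / 4)
  A[3, 1:3] <- c(17 / 50, -1 / 25, 1 / 4)
  A[4, 1:4] <- c(371 / 1360, -137 / 2720, 15 / 544, 1 / 4)
  A[5, 1:5] <- c(25 / 24, -49 / 48, 125 / 16, -85 / 12, 1 / 4)
  b <- A[5, ]
  cc <- rowSums(A)
  expect_equal(cc, c(1 / 4, 3 / 4, 11 / 20, 1 / 2, 1))
  expect_equal(sum(b), 1)
  expect_equal(sum(b * cc), 1 / 2)
  expect_equal(sum(b * cc^2), 1 / 3)
  expect_equal(sum(b * (A %*% cc)), 1 / 6)
  expect_equal(sum(b * cc^3), 1 / 4)
  expect_equal(sum(b * cc * (A %*% cc)), 1 / 8)
  expect_equal(sum(b * (A %*% cc^2)), 1 / 12)
  expect_equal(sum(b * (A %*% A %*% cc)), 1 / 24)
  # stability function R(z) -> 0 as z -> -infinity (L-stability)
  z <- -1e9
  expect_lt(abs(1 + z * sum(b * solve(diag(5) - z * A, rep(1, 5)))), 1e-6)
  # embedded order-3 weights
  bh <- c(59 / 48, -17 / 96, 225 / 32, -85 / 12, 0)
  expect_equal(sum(bh), 1)
  expect_equal(sum(bh * cc), 1 / 2)
  expect_equal(sum(bh * cc^2), 1 / 3)
  expect_equal(sum(bh * (A %*% cc)), 1 / 6)
})

test_that("implicit and explicit integration agree in the stiff regime", {
  # at F_sh = 0.8 the capillary O2 rate (~1050 1/s) routes the adaptive
  # solver through the implicit stepper; a fine fixed-step RK4 reference
  # (stable at dt = 5e-5 s) must agree
  cfg <- default_config(F_sh = 0.8, F_ds = 0.1)
  ss <- run_to_steady_state(cfg)
  sim <- simulate_evlp(cfg, duration = 9, init = ss$state, fd0 = ss$fd)
  pv <- evlpsim:::config_to_pars(cfg)
  ref <- evlpsim:::cpp_simulate_fixed(pv, unname(ss$state), ss$fd, 0, 9,
                                      5e-5, seq(0, 9, by = 0.05), 0L)
  i <- round(ref$time / 0.01) + 1L
  expect_lt(max(abs(sim$states[i, "P_c_O2"] - ref$states[, 4])), 0.05)
  expect_lt(max(abs(sim$states[i, "F_A_O2"] - ref$states[, 2])), 1e-5)
})

test_that("plug-flow mixing starves the alveoli of fresh gas under the
           ramp ventilator", {
  # the dilution/plug contrast documented in the methods vignette: at
  # defaults plug flow lowers oxygenation and retains CO2 relative to
  # dilution mixing...
  ssd <- run_to_steady_state(default_cfg)
  ssp <- run_to_steady_state(default_cfg, mixing = "plug",
                             max_time = 2000)
  expect_lt(ssp$P_LA_O2, ssd$P_LA_O2 - 5)
  expect_gt(ssp$P_LA_CO2, ssd$P_LA_CO2 + 3)
  # ...and with the calibrated parameter set (V_D above the delivered
  # volume) no fresh gas arrives at all: metabolism drives the alveolar
  # O2 fraction out of the physically valid region
  expect_error(
    run_to_steady_state(update_config(calibrated_cfg, FiO2 = 0.21),
                        mixing = "plug", max_time = 2000),
    "physically valid|steady state")
})

test_that("degenerate configurations fail fast with a diagnostic error", {
  # 95% shunt starves the gas-exchange compartment: metabolic demand
  # exceeds supply and the state exits the physically valid region
  cfg <- default_config(F_sh = 0.95, F_ds = 0.049, Q = 0.5,
                        P_PA_O2 = 40)
  expect_error(
    run_to_steady_state(cfg, max_time = 3600),
    "physically valid|steady state")
})

test_that("steady state is reached, idempotent, and independent of the
           initial conditions", {
  ss <- run_to_steady_state(default_cfg, tol = 0.002, max_time = 2000)
  expect_true(ss$converged)
  # idempotence: restarting from the converged state ends within 2 cycles
  ss2 <- run_to_steady_state(default_cfg, init = ss$state, tol = 0.002)
  expect_lte(ss2$n_cycles, 2)
  # perturbing each initial state by +/-20% leaves the converged cycle
  # means essentially unchanged
  for (j in c("F_A_O2", "P_c_O2", "z")) {
    init <- initial_state()
    init[j] <- init[j] * 1.2
    ssp <- run_to_steady_state(default_cfg, init = init, tol = 0.002,
                               max_time = 2000)
    expect_lt(abs(ssp$P_LA_O2 - ss$P_LA_O2), 0.1)
    expect_lt(abs(ssp$P_LA_CO2 - ss$P_LA_CO2), 0.1)
  }
  # the cap raises an informative error
  expect_error(run_to_steady_state(default_cfg, tol = 1e-9,
                                   max_time = 30),
               "steady state")
})

test_that("state invariants hold along trajectories from the default
           initial conditions", {
  for (cfg in random_configs(4, seed = 11)) {
    sim <- simulate_evlp(cfg, duration = 30)
    expect_true(all(is.finite(sim$states)))
    expect_true(all(sim$states[, "F_A_O2"] >= 0 &
                      sim$states[, "F_A_O2"] <= 1))
    expect_true(all(sim$states[, "F_A_CO2"] >= 0 &
                      sim$states[, "F_A_CO2"] <= 1))
    expect_true(all(sim$states[, "F_A_O2"] + sim$states[, "F_A_CO2"] <= 1))
    expect_true(all(sim$states[, c("P_c_O2", "P_c_CO2")] >= 0))
    expect_true(all(sim$states[, "z"] >= 0))
  }
})

test_that("schedules apply piecewise-constant input steps continuously", {
  ss <- run_to_steady_state(default_cfg)
  sched <- fio2_challenge_schedule(step_time = 10, fio2 = 1.0)
  sim <- simulate_evlp(default_cfg, duration = 60, schedule = sched,
                       init = ss$state, fd0 = ss$fd)
  i_step <- which.min(abs(sim$time - 10))
  # state continuity across the step
  expect_lt(abs(sim$P_LA_O2[i_step + 1] - sim$P_LA_O2[i_step]), 0.5)
  # oxygenation rises markedly after the step
  expect_gt(sim$P_LA_O2[length(sim$time)], sim$P_LA_O2[i_step] + 30)
  expect_error(input_schedule(10, "F_sh", 0.3), "clinical")
  expect_error(input_schedule(c(5, 1), c("FiO2", "FiO2"), c(0.3, 0.4)),
               "non-decreasing")
})

test_that("the 100 Hz output grid is uniform and complete", {
  sim <- simulate_evlp(default_cfg, duration = 2)
  expect_equal(diff(sim$time), rep(0.01, 200), tolerance = 1e-9)
  expect_identical(length(sim$time), 201L)
})

test_that("nearest-neighbour resampling uses the earlier-index tie rule", {
  grid <- seq(0, 1, by = 0.1)
  vals <- seq_along(grid)
  expect_equal(resample_nearest(grid, 0.3, vals), 4)
  expect_equal(resample_nearest(grid, 0.35, vals), 4)  # tie -> earlier
  expect_equal(resample_nearest(grid, 0.351, vals), 5)
  expect_error(resample_nearest(grid, 1.2, vals), "span")
  # 3-s grid over 15 min -> 301 samples
  sim <- simulate_evlp(default_cfg, duration = 900, dt_out = 3)
  out <- resample_nearest(sim, seq(0, 900, by = 3))
  expect_identical(nrow(out), 301L)
})

test_that("static scenarios reproduce the canonical orderings", {
  sc <- run_static_scenarios()
  base <- sc[sc$scenario == "baseline", ]
  hds <- sc[sc$scenario == "high_deadspace", ]
  hsh <- sc[sc$scenario == "high_shunt", ]
  dq <- sc[sc$scenario == "double_flow", ]
  # shunt depresses oxygenation more than dead space
  expect_lt(hsh$mean_P_LA_O2, hds$mean_P_LA_O2)
  expect_lt(hds$mean_P_LA_O2, base$mean_P_LA_O2)
  # dead space raises CO2 more than shunt
  expect_gt(hds$mean_P_LA_CO2, hsh$mean_P_LA_CO2)
  expect_gt(hsh$mean_P_LA_CO2, base$mean_P_LA_CO2)
  # doubling flow: less oxygen uptake, more CO2 delivery
  expect_lt(dq$mean_P_LA_O2, base$mean_P_LA_O2)
  expect_gt(dq$mean_P_LA_CO2, base$mean_P_LA_CO2)
})
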